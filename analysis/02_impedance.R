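#!/usr/bin/env Rscript
# Step 2: unsteady resistance of the cervical canal.
#
# Reads the geometries and waveform generated by 01_simulate.R, computes the
# longitudinal impedance spectrum over the 0-25 mm segment, the 1-8 Hz ILI,
# the reconstructed pressure-drop trace, and the inlet peak Reynolds number.
# Writes tables under results/impedance/ and a spectrum/trace figure when
# ggplot2 is available.

suppressMessages(library(csfmotion))
out <- "results/impedance"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
stopifnot(file.exists("results/data/waveform.csv"))

wave <- read_waveform_csv("results/data/waveform.csv")
geos <- list(cmi_like = make_geometry(crowding_factor = 0.4),
             uncrowded = make_geometry(crowding_factor = 0))

rows <- lapply(names(geos), function(nm) {
  g <- geos[[nm]]
  sp <- impedance_spectrum(g, seq(1, 8, length.out = 29))
  res <- compute_ili(sp)
  write_spectrum(sp, file.path(out, paste0("spectrum_", nm)), res)
  m0 <- section_metrics(g$sections[[1]])
  data.frame(geometry = nm, ili_dyn_cm5 = res$ili,
             steady_resistance = steady_resistance(g),
             inlet_dh_cm = m0$dh_cm,
             inlet_peak_reynolds = reynolds_number(max(wave$samples_Q),
                                                   fluid_props(), m0))
})
tab <- do.call(rbind, rows)
utils::write.csv(tab, file.path(out, "ili_summary.csv"), row.names = FALSE)
print(tab, row.names = FALSE)

# pressure-drop trace for the crowded geometry (the Fig.-2-style panels)
tr <- reconstruct_pressure_trace(geos$cmi_like, wave)
n <- wave$n_samples
traces <- data.frame(time_s = (seq_len(n) - 1) * wave$period_T / n,
                     flow_cm3_per_s = wave$samples_Q,
                     pressure_drop_dyn_cm2 = tr$delta_P)
utils::write.csv(traces, file.path(out, "pressure_flow_traces.csv"),
                 row.names = FALSE)
message("peak-to-peak pressure drop: ",
        round(diff(range(tr$delta_P)), 1), " dyn/cm^2")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  sp <- impedance_spectrum(geos$cmi_like, seq(1, 8, length.out = 29))
  p1 <- ggplot(data.frame(f = sp$frequencies, z = Mod(sp$Z_L)),
               aes(f, z)) + geom_line() +
    labs(x = "frequency (Hz)", y = "|Z_L| (dyn s/cm^5)",
         title = "Longitudinal impedance, 0-25 mm segment")
  p2 <- ggplot(traces, aes(time_s, pressure_drop_dyn_cm2)) + geom_line() +
    labs(x = "time (s)", y = "pressure drop (dyn/cm^2)")
  p3 <- ggplot(traces, aes(time_s, flow_cm3_per_s)) + geom_line() +
    labs(x = "time (s)", y = "flow (cm^3/s)")
  pdf(file.path(out, "impedance_panels.pdf"), width = 6, height = 9)
  print(p1); print(p2); print(p3)
  dev.off()
}
message("done: ", out)
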