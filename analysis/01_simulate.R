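#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs with known ground truth.
#
# Produces, under results/data/:
#   - a crowded ("CMI-like") and an uncrowded canal geometry (per-slice
#     hydraulic metrics as CSV)
#   - the default CSF flow waveform (CSV)
#   - one DENSE motion phantom (displacement summary ground truth as JSON)
#   - a coupled synthetic cohort of 32 CMI subjects and 18 controls (CSV)
#
# Everything is seeded; rerunning reproduces the files byte-for-byte.

suppressMessages(library(csfmotion))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Canal geometries (annular, 0-60 mm, crowding narrows the first 25 mm)")
geo_cmi <- make_geometry(crowding_factor = 0.4)
geo_ctl <- make_geometry(crowding_factor = 0)
write_section_metrics(geo_cmi, file.path(out, "geometry_cmi_metrics.csv"))
write_section_metrics(geo_ctl, file.path(out, "geometry_control_metrics.csv"))
message("  inlet D_H (crowded): ",
        round(section_metrics(geo_cmi$sections[[1]])$dh_cm, 3), " cm")

message("CSF flow waveform (86.3 bpm, 100 samples, peak 2.5 cm^3/s)")
wave <- make_waveform()
write_waveform_csv(wave, file.path(out, "waveform.csv"))

message("DENSE phantom (gaussian bump, 300 um peak, SNR 20, seed 1)")
ph <- make_dense_phantom(seed = 1)
write_displacement_summary(ph$truth_summary,
                           file.path(out, "phantom_truth_summary"),
                           subject = "phantom-seed1")
message("  truth ROI displacement (cerebellum): ",
        round(ph$truth_summary$cerebellum$displacement_um, 1), " um")

message("Synthetic cohort (32 CMI / 18 controls, coupled, seed 1)")
rec <- make_cohort(seed = 1)
write_cohort_csv(rec, file.path(out, "cohort_records.csv"))
lat <- attr(rec, "latent")
utils::write.csv(lat, file.path(out, "cohort_latent_truth.csv"),
                 row.names = FALSE)
message("  CMI ILI ", round(mean(rec$ili_dyn_cm5[rec$group == "CMI"])),
        " +/- ", round(stats::sd(rec$ili_dyn_cm5[rec$group == "CMI"])),
        " dyn/cm^5; control ",
        round(mean(rec$ili_dyn_cm5[rec$group == "control"])), " +/- ",
        round(stats::sd(rec$ili_dyn_cm5[rec$group == "control"])))
message("done: ", out)
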