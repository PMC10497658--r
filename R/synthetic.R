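# Synthetic-data generators: canal geometries, CSF flow waveforms, DENSE
# motion phantoms, and cohorts with a controllable ILI-displacement
# relationship. Every generator is deterministic under a fixed seed and
# emits its ground truth.

#' Rasterize a (possibly eccentric) annular cross-section
#'
#' Builds a binary lumen raster together with its exact signed distance
#' field and fractional pixel coverage, which enable sub-pixel boundary
#' treatment downstream. `inner_radius = 0` gives a disc.
#'
#' @param outer_radius,inner_radius radii in cm.
#' @param pixel_spacing raster spacing in mm.
#' @param eccentricity offset of the inner circle centre in cm.
#' @param z axial position in mm.
#' @return A [cross_section()].
#' @export
rasterize_annulus <- function(outer_radius, inner_radius = 0,
                              pixel_spacing = 0.4, eccentricity = 0, z = 0) {
  if (inner_radius < 0 || outer_radius <= inner_radius)
    stop("need 0 <= inner_radius < outer_radius")
  px <- pixel_spacing / 10  # cm
  half <- outer_radius + 3 * px
  n <- 2L * ceiling(half / px) + 1L
  xs <- (seq_len(n) - (n + 1L) / 2) * px
  X <- matrix(xs, n, n); Y <- t(X)
  r_out <- sqrt(X^2 + Y^2)
  sdf <- outer_radius - r_out
  if (inner_radius > 0) {
    r_in <- sqrt((X - eccentricity)^2 + Y^2)
    sdf <- pmin(sdf, r_in - inner_radius)
  }
  sdf <- matrix(sdf, n, n)
  coverage <- matrix(pmin(1, pmax(0, 0.5 + sdf / px)), n, n)
  cross_section(sdf >= 0, pixel_spacing, z,
                sdf = sdf * 10,  # store in mm
                coverage = coverage)
}

#' Synthetic canal geometry with tonsillar crowding
#'
#' An annular canal from the foramen magnum (z = 0) to `extent` mm caudal.
#' `crowding_factor` narrows the annular gap over the first 25 mm, emulating
#' tonsillar crowding of the craniocervical junction: by default the full
#' narrowing is held over the first 10 mm and recovers linearly by 25 mm
#' (`profile = "plateau"`); `profile = "linear"` recovers linearly from z = 0.
#'
#' @param outer_radius dural radius in cm.
#' @param inner_radius cord radius in cm (uncrowded); the gap narrows by
#'   growing the inner body.
#' @param eccentricity inner-body centre offset in cm (must stay below the
#'   local gap).
#' @param crowding_factor fractional gap narrowing in \[0, 1).
#' @param pixel_spacing raster spacing in mm.
#' @param slice_z axial slice positions in mm (must start at 0 and reach 25);
#'   default places six slices over 0-25 mm and three more to `extent`.
#' @param extent caudal extent in mm.
#' @param profile crowding recovery profile.
#' @return A [canal_geometry()]; deterministic in its arguments.
#' @export
make_geometry <- function(outer_radius = 1.0, inner_radius = 0.64,
                          eccentricity = 0, crowding_factor = 0.4,
                          pixel_spacing = 0.4, slice_z = NULL, extent = 60,
                          profile = c("plateau", "linear")) {
  profile <- match.arg(profile)
  if (inner_radius <= 0 || inner_radius >= outer_radius)
    stop("inner_radius must lie strictly between 0 and outer_radius")
  if (crowding_factor < 0 || crowding_factor >= 1)
    stop("crowding_factor must lie in [0, 1)")
  if (is.null(slice_z))
    slice_z <- c(seq(0, 25, length.out = 6L),
                 seq(25, extent, length.out = 4L)[-1L])
  if (abs(slice_z[1L]) > 1e-9 || max(slice_z) < 25)
    stop("slice_z must start at 0 and reach at least 25 mm")
  g0 <- outer_radius - inner_radius
  ramp <- function(z) {
    if (profile == "linear") pmax(0, 1 - z / 25)
    else ifelse(z <= 10, 1, pmax(0, (25 - z) / 15))
  }
  secs <- lapply(slice_z, function(z) {
    gap <- g0 * (1 - crowding_factor * ramp(z))
    if (gap <= 0) stop("lumen pinched closed at z = ", z, " mm")
    if (eccentricity > gap - 1e-12)
      stop("eccentricity (", eccentricity,
           " cm) exceeds the annular gap at z = ", z, " mm (", signif(gap, 3),
           " cm)")
    rasterize_annulus(outer_radius, outer_radius - gap, pixel_spacing,
                      eccentricity, z)
  })
  canal_geometry(secs)
}

#' Synthetic CSF flow waveform
#'
#' Zero-mean periodic pulse built from a truncated 4-harmonic series with a
#' systolic peak, scaled to the requested peak flow. Defaults match a heart
#' rate of 86.3 bpm sampled at 100 steps per cycle.
#'
#' @param heart_rate_bpm heart rate in beats per minute.
#' @param peak_flow_cm3_s peak volumetric flow in cm^3/s (> 0).
#' @param n_samples samples per cycle (>= 16).
#' @param shape_seed optional seed perturbing the harmonic amplitudes and
#'   phases, giving a different waveform shape.
#' @return A [flow_waveform()].
#' @export
make_waveform <- function(heart_rate_bpm = 86.3, peak_flow_cm3_s = 2.5,
                          n_samples = 100L, shape_seed = NULL) {
  if (heart_rate_bpm <= 0) stop("heart rate must be positive")
  if (peak_flow_cm3_s <= 0) stop("peak flow must be positive")
  if (n_samples < 16L) stop("waveform needs at least 16 samples")
  period <- 60 / heart_rate_bpm
  amp <- c(1, 0.45, 0.22, 0.10)
  pha <- c(0, 0.8, 1.6, 2.4)
  if (!is.null(shape_seed)) {
    pert <- with_seed(shape_seed,
                      list(a = stats::runif(4L, 0.7, 1.3),
                           p = stats::runif(4L, -0.6, 0.6)))
    amp <- amp * pert$a
    pha <- pha + pert$p
  }
  t <- (seq_len(n_samples) - 1L) / n_samples
  q <- rowSums(sapply(1:4, function(k) amp[k] * cos(2 * pi * k * t - pha[k])))
  flow_waveform(q * peak_flow_cm3_s / max(q), period_T = period)
}

# Phantom anatomy: a cerebellum disc and a brainstem ellipse on the image
# grid, in mm relative to the image centre.
phantom_regions <- function(n_pixels, pixel_size) {
  xs <- (seq_len(n_pixels) - n_pixels / 2) * pixel_size
  X <- matrix(xs, n_pixels, n_pixels); Y <- t(X)
  cer <- sqrt((X + 10)^2 + (Y - 8)^2) <= 14
  bst <- ((X - 12)^2 / 6^2 + Y^2 / 16^2) <= 1
  lab <- matrix(0L, n_pixels, n_pixels)
  lab[bst] <- 2L
  lab[cer] <- 1L  # cerebellum wins overlaps
  list(labels = lab, X = X, Y = Y,
       centers = list(cerebellum = c(-10, 8), brainstem = c(12, 0)))
}

#' Synthetic cine DENSE phantom with known motion
#'
#' Emulates a cyclical-motion tissue phantom: a smooth displacement field
#' (uniform, or Gaussian bumps centred in the cerebellum and brainstem
#' regions) driven by a smooth periodic pulse, encoded into wrapped image
#' phase at the given encoding frequency, with complex-channel Gaussian
#' noise at the requested magnitude SNR. The ground-truth displacement maps
#' and their ROI summaries accompany the series.
#'
#' The bump scale defaults to 12 mm so the spatial content of the motion
#' lies within the passband of the standard displacement noise filter, as
#' tissue-scale cardiac motion does.
#'
#' @param peak_displacement cerebellar peak displacement in um; must stay
#'   below half the encoding wavelength (1/(2 ke) = 833 um at the default
#'   ke) unless `allow_wrap = TRUE`.
#' @param pattern "gaussian_bump" (default) or "uniform".
#' @param bump_sigma_mm Gaussian bump scale in mm.
#' @param brainstem_peak brainstem bump peak in um (gaussian_bump pattern).
#' @param snr magnitude signal-to-noise ratio of the tissue signal; `Inf`
#'   disables noise.
#' @param phase_noise_sd alternative noise model: additive phase noise in
#'   radians (overrides `snr`).
#' @param seed RNG seed (restored on exit).
#' @param n_pixels,pixel_size image grid (default 72 px at 0.9 mm).
#' @param frame_interval frame duration in ms.
#' @param ke encoding frequency in cycles/mm.
#' @param heart_rate_bpm sets the cycle length, hence the frame count.
#' @param allow_wrap permit displacements beyond the unambiguous range (for
#'   wrap testing).
#' @return An object of class `dense_phantom`: list with `series`
#'   ([dense_series()]), `mask` ([region_mask()]), `truth_maps`
#'   (`displacement_maps` of the noise-free truth), `truth_summary` (named
#'   list of [summarize_region()] results on the truth), and `params`.
#' @export
make_dense_phantom <- function(peak_displacement = 300,
                               pattern = c("gaussian_bump", "uniform"),
                               bump_sigma_mm = 12, brainstem_peak = 180,
                               snr = 20, phase_noise_sd = NULL, seed = NULL,
                               n_pixels = 72L, pixel_size = 0.9,
                               frame_interval = 34, ke = 0.6,
                               heart_rate_bpm = 86.3, allow_wrap = FALSE) {
  pattern <- match.arg(pattern)
  if (peak_displacement <= 0) stop("peak displacement must be positive")
  half_wave <- 1000 / (2 * ke)
  if (!allow_wrap && peak_displacement >= half_wave)
    stop("peak displacement ", peak_displacement,
         " um reaches half the encoding wavelength (", round(half_wave, 1),
         " um); set allow_wrap = TRUE for wrap testing")
  geo <- phantom_regions(n_pixels, pixel_size)
  mask <- region_mask(geo$labels, pixel_size,
                      c(cerebellum = 1L, brainstem = 2L))
  period_ms <- 60 / heart_rate_bpm * 1000
  nf <- max(2L, floor(period_ms / frame_interval))
  tms <- (seq_len(nf) - 1L) * frame_interval
  w <- exp(-((tms / period_ms - 0.35) / 0.15)^2)
  w <- w / max(w)
  if (pattern == "uniform") {
    u0 <- matrix(peak_displacement, n_pixels, n_pixels)
  } else {
    cc <- geo$centers$cerebellum; cb <- geo$centers$brainstem
    u0 <- peak_displacement *
      exp(-((geo$X - cc[1L])^2 + (geo$Y - cc[2L])^2) / (2 * bump_sigma_mm^2)) +
      brainstem_peak *
      exp(-((geo$X - cb[1L])^2 + (geo$Y - cb[2L])^2) / (2 * 8^2))
  }
  theta <- pi / 4  # motion split equally between AP and CC
  truth_ap <- array(0, c(n_pixels, n_pixels, nf))
  truth_cc <- array(0, c(n_pixels, n_pixels, nf))
  for (k in seq_len(nf)) {
    truth_ap[, , k] <- u0 * w[k] * cos(theta)
    truth_cc[, , k] <- u0 * w[k] * sin(theta)
  }
  mag0 <- 30 + 70 * (geo$labels > 0L)
  magnitude <- array(rep(mag0, nf), c(n_pixels, n_pixels, nf))
  ph_ap <- wrap_phase(2 * pi * ke * truth_ap / 1000)
  ph_cc <- wrap_phase(2 * pi * ke * truth_cc / 1000)
  with_seed(seed, {
    if (!is.null(phase_noise_sd)) {
      if (phase_noise_sd > 0) {
        ph_ap <- wrap_phase(ph_ap + stats::rnorm(length(ph_ap), 0, phase_noise_sd))
        ph_cc <- wrap_phase(ph_cc + stats::rnorm(length(ph_cc), 0, phase_noise_sd))
      }
    } else if (is.finite(snr)) {
      sdn <- 100 / snr  # tissue magnitude is 100 a.u.
      noisy <- function(ph) {
        z <- c(magnitude) * exp(1i * c(ph)) +
          complex(real = stats::rnorm(length(ph), 0, sdn),
                  imaginary = stats::rnorm(length(ph), 0, sdn))
        list(ph = array(Arg(z), dim(ph)), mag = array(Mod(z), dim(ph)))
      }
      na <- noisy(ph_ap); nc <- noisy(ph_cc)
      ph_ap <- na$ph; ph_cc <- nc$ph
      magnitude <- (na$mag + nc$mag) / 2
    }
  })
  series <- dense_series(magnitude, ph_ap, ph_cc, pixel_size, frame_interval,
                         ke)
  truth_maps <- structure(list(ap = truth_ap, cc = truth_cc,
                               validity = matrix(TRUE, n_pixels, n_pixels),
                               pixel_size = pixel_size,
                               frame_interval = frame_interval),
                          class = "displacement_maps")
  me <- erode_region(mask, 2L)
  truth_summary <- lapply(names(mask$region_names), function(nm)
    summarize_region(truth_maps, me, nm))
  names(truth_summary) <- names(mask$region_names)
  structure(list(series = series, mask = mask, truth_maps = truth_maps,
                 truth_summary = truth_summary,
                 params = list(peak_displacement = peak_displacement,
                               pattern = pattern,
                               bump_sigma_mm = bump_sigma_mm,
                               brainstem_peak = brainstem_peak, snr = snr,
                               phase_noise_sd = phase_noise_sd, seed = seed,
                               n_frames = nf)),
            class = "dense_phantom")
}

# --- cohort generator -------------------------------------------------------

# crowding -> ILI calibration curve, memoised per geometry settings (the
# curve is deterministic; recomputing it per seed would dominate run time).
.calib_cache <- new.env(parent = emptyenv())

cohort_calibration <- function(gp) {
  key <- paste(gp$outer_radius, gp$inner_radius, gp$pixel_spacing,
               paste(gp$slice_z, collapse = ","), gp$crowding_max,
               gp$n_freq, gp$freq_interp_n, sep = "|")
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  grid <- seq(0, gp$crowding_max, length.out = 9L)
  vals <- vapply(grid, function(cr) {
    g <- make_geometry(gp$outer_radius, gp$inner_radius,
                       crowding_factor = cr,
                       pixel_spacing = gp$pixel_spacing,
                       slice_z = gp$slice_z)
    ili(g, n_freq = gp$n_freq, freq_interp_n = gp$freq_interp_n)$ili
  }, numeric(1))
  if (any(diff(vals) <= 0))
    stop("calibration curve is not monotone; geometry settings unusable")
  fine_c <- seq(0, gp$crowding_max, length.out = 400L)
  fine_l <- stats::spline(grid, log(vals), xout = fine_c, method = "hyman")$y
  cal <- list(crowding = fine_c, log_ili = fine_l,
              range = range(vals))
  .calib_cache[[key]] <- cal
  cal
}

lognormal_pars <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

#' Synthetic subject cohort with a crowding-driven ILI-displacement link
#'
#' Per subject, a latent crowding factor drives the canal geometry, hence
#' ILI through the impedance pipeline; in the `"coupled"` mode the same
#' latent also drives cerebellar displacement (CMI group), while brainstem
#' displacement is independent noise in every mode, so no brainstem
#' correlation is induced. `"decoupled"` severs the cerebellar link (null
#' model); `"graded"` shrinks the cerebellar noise with increasing latent
#' crowding, so the ILI-displacement correlation strengthens among
#' high-displacement subjects.
#'
#' Crowding factors are assigned by drawing per-subject target ILI values
#' from moment-matched lognormals and inverting a crowding-to-ILI
#' calibration curve computed with the same pipeline settings, so achieved
#' group moments track the requested ones; draws outside the attainable
#' range are clamped (a warning reports the clamped fraction when large).
#'
#' @param n_cmi,n_control group sizes (>= 2 each; defaults 32 and 18).
#' @param seed RNG seed.
#' @param coupling "coupled" (default), "decoupled" or "graded".
#' @param ili_moments,cer_moments,bst_moments per-group `c(mean, sd)` targets
#'   for ILI (dyn/cm^5) and cerebellar/brainstem displacement (um).
#' @param rho_cer latent-displacement correlation per group (coupled mode).
#' @param geometry list of cohort geometry settings: `outer_radius`,
#'   `inner_radius` (cm), `pixel_spacing` (mm), `slice_z` (mm),
#'   `crowding_max`, `n_freq`, `freq_interp_n`.
#' @param include_symptoms attach the five symptom flags (CMI, drawn at
#'   typical reported frequencies) and MPQ/DIQ scores.
#' @param props [fluid_props()].
#' @return Subject records data frame (see [cohort_report()]) with
#'   attributes `latent` (per-subject crowding, latent z and target ILI) and
#'   `generator` (settings); fully reproducible under `seed`.
#' @export
make_cohort <- function(n_cmi = 32L, n_control = 18L, seed = NULL,
                        coupling = c("coupled", "decoupled", "graded"),
                        ili_moments = list(CMI = c(485, 184),
                                           control = c(244, 38)),
                        cer_moments = list(CMI = c(294, 240),
                                           control = c(128, 42)),
                        bst_moments = list(CMI = c(234, 101),
                                           control = c(154, 44)),
                        rho_cer = c(CMI = 0.8, control = 0),
                        geometry = list(), include_symptoms = TRUE,
                        props = fluid_props()) {
  coupling <- match.arg(coupling)
  if (n_cmi < 2L || n_control < 2L) stop("need at least 2 subjects per group")
  gp <- utils::modifyList(
    list(outer_radius = 1.1, inner_radius = 0.52, pixel_spacing = 0.5,
         slice_z = c(0, 10, 25, 60), crowding_max = 0.88,
         n_freq = 29L, freq_interp_n = 9L),
    geometry)
  cal <- cohort_calibration(gp)
  groups <- c(rep("CMI", n_cmi), rep("control", n_control))
  n <- length(groups)
  with_seed(seed, {
    z_lat <- stats::rnorm(n)
    eps_cer <- stats::rnorm(n)
    eps_bst <- stats::rnorm(n)
    crowding <- numeric(n)
    ili_val <- numeric(n)
    n_clamped <- 0L
    for (i in seq_len(n)) {
      lp <- lognormal_pars(ili_moments[[groups[i]]][1L],
                           ili_moments[[groups[i]]][2L])
      target <- exp(lp["mu"] + lp["sigma"] * z_lat[i])
      lt <- log(target)
      if (lt <= min(cal$log_ili) || lt >= max(cal$log_ili)) n_clamped <- n_clamped + 1L
      crowding[i] <- stats::approx(cal$log_ili, cal$crowding, xout = lt,
                                   rule = 2)$y
      geom <- make_geometry(gp$outer_radius, gp$inner_radius,
                            crowding_factor = crowding[i],
                            pixel_spacing = gp$pixel_spacing,
                            slice_z = gp$slice_z)
      ili_val[i] <- ili(geom, props = props, n_freq = gp$n_freq,
                        freq_interp_n = gp$freq_interp_n)$ili
    }
    if (n_clamped > 0.15 * n)
      warning("ILI moment targets only partially attainable: ", n_clamped,
              " of ", n, " subjects clamped to the calibration range [",
              paste(round(cal$range), collapse = ", "), "] dyn/cm^5")
    # latent standardised on the achieved ILI scale
    disp_cer <- disp_bst <- numeric(n)
    for (i in seq_len(n)) {
      g <- groups[i]
      lp <- lognormal_pars(ili_moments[[g]][1L], ili_moments[[g]][2L])
      z_eff <- (log(ili_val[i]) - lp["mu"]) / lp["sigma"]
      e <- eps_cer[i]
      if (coupling == "graded" && g == "CMI") {
        # coupling strength grows with displacement: above the 45th latent
        # percentile displacement lies exactly on a line in ILI; below it a
        # downward-only disturbance (e.g. compliance variation dissipating
        # motion) scatters subjects off the line, so subset correlations
        # strengthen as the displacement cutoff rises
        beta <- 1.3
        alpha <- cer_moments[[g]][1L] - beta * ili_moments[[g]][1L]
        det <- max(20, alpha + beta * ili_val[i])
        w <- stats::pnorm(z_eff)
        tau <- 1.5 * max(0, (0.45 - w) / 0.45)
        disp_cer[i] <- max(15, det * exp(-tau * abs(e)))
      } else {
        rho <- if (coupling == "decoupled") 0 else unname(rho_cer[g])
        y <- rho * z_eff + sqrt(1 - rho^2) * e
        dp <- lognormal_pars(cer_moments[[g]][1L], cer_moments[[g]][2L])
        disp_cer[i] <- exp(dp["mu"] + dp["sigma"] * y)
      }
      bp <- lognormal_pars(bst_moments[[g]][1L], bst_moments[[g]][2L])
      disp_bst[i] <- exp(bp["mu"] + bp["sigma"] * eps_bst[i])
    }
    records <- data.frame(
      id = sprintf("S%03d", seq_len(n)), group = groups,
      ili_dyn_cm5 = ili_val, disp_cerebellum_um = disp_cer,
      disp_brainstem_um = disp_bst, stringsAsFactors = FALSE)
    if (include_symptoms) {
      pflag <- c(imbalance = 12, vertigo = 19, swallowing = 16,
                 nausea_vomiting = 16, hoarseness = 13) / 31
      for (s in names(pflag)) {
        v <- rep(NA, n)
        v[groups == "CMI"] <- stats::runif(n_cmi) < pflag[[s]]
        records[[s]] <- v
      }
      if (n_cmi > 1L) {
        drop1 <- sample(which(groups == "CMI"), 1L)
        records[drop1, names(pflag)] <- NA  # one CMI subject unassessed
      }
      nq <- round(n_cmi * 25 / 32)
      qi <- sample(which(groups == "CMI"), nq)
      records$mpq <- rep(NA_real_, n)
      records$diq <- rep(NA_real_, n)
      records$mpq[qi] <- pmax(1, stats::rnorm(nq, 106.9, 51.5))
      records$diq[qi] <- pmax(1, stats::rnorm(nq, 50.9, 17.9))
    }
    attr(records, "latent") <- data.frame(
      id = records$id, crowding = crowding, z_latent = z_lat,
      ili = ili_val)
    attr(records, "generator") <- c(gp, list(coupling = coupling, seed = seed))
    validate_records(records)
    records
  })
}

#' Rebuild the canal geometry of one cohort subject
#'
#' Uses the generator settings and latent crowding stored on the records.
#'
#' @param records a [make_cohort()] result.
#' @param id subject id (e.g. "S001").
#' @return The subject's [canal_geometry()].
#' @export
subject_geometry <- function(records, id) {
  lat <- attr(records, "latent"); gp <- attr(records, "generator")
  if (is.null(lat) || is.null(gp)) stop("records carry no generator metadata")
  i <- match(id, lat$id)
  if (is.na(i)) stop("unknown subject id: ", id)
  make_geometry(gp$outer_radius, gp$inner_radius,
                crowding_factor = lat$crowding[i],
                pixel_spacing = gp$pixel_spacing, slice_z = gp$slice_z)
}
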