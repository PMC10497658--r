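# Longitudinal impedance of the cervical CSF space.
#
# The 3D transient CFD of the original workflow is replaced by a slice-wise
# fully developed oscillatory flow model: on each cross-section the axial
# velocity of a harmonic at angular frequency w obeys
#
#     i w rho u = G + mu Laplacian(u),   u = 0 on the walls,
#
# with G the (spatially uniform) axial pressure gradient. The complex
# "mobility" of a slice is the volumetric flow per unit pressure gradient;
# the longitudinal impedance of a segment is the line integral of 1/mobility
# along z, which makes Z_L additive over contiguous segments by construction
# and independent of the driving waveform.

#' A periodic CSF volumetric flow waveform
#'
#' @param samples_Q volumetric flow in cm^3/s, uniformly sampled over one
#'   cardiac period (at least 16 samples).
#' @param period_T cardiac period in s; default 60/86.3 (86.3 bpm).
#' @return An object of class `flow_waveform`.
#' @export
flow_waveform <- function(samples_Q, period_T = 60 / 86.3) {
  if (!is.numeric(samples_Q) || length(samples_Q) < 16L)
    stop("waveform needs at least 16 samples")
  if (anyNA(samples_Q)) stop("waveform contains NA")
  if (!is.numeric(period_T) || period_T <= 0) stop("period must be positive")
  structure(list(samples_Q = as.numeric(samples_Q), period_T = period_T,
                 n_samples = length(samples_Q)),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("Flow waveform: %d samples over T = %.4f s (peak %.3g cm^3/s)\n",
              x$n_samples, x$period_T, max(abs(x$samples_Q))))
  invisible(x)
}

#' Womersley number
#'
#' `alpha = R * sqrt(omega * rho / mu)` for a characteristic radius R (cm)
#' at frequency f (Hz).
#'
#' @param radius_cm characteristic radius in cm.
#' @param frequency_f frequency in Hz.
#' @param props [fluid_props()].
#' @return Dimensionless Womersley number.
#' @export
womersley_number <- function(radius_cm, frequency_f, props = fluid_props()) {
  radius_cm * sqrt(2 * pi * frequency_f * props$density_rho /
                     props$viscosity_mu)
}

# --- discrete operator ------------------------------------------------------

# Shortley-Weller Laplacian on the lumen pixels of a section (units 1/cm^2).
# Wall distances along grid links come from the signed distance field when
# available (sub-pixel boundary); for purely binary masks the wall is placed
# half a pixel beyond the last lumen pixel centre.
assemble_lumen_operator <- function(section) {
  mask <- section$lumen_mask
  h <- section$pixel_spacing / 10  # cm
  nr <- nrow(mask)
  idx <- which(mask)
  N <- length(idx)
  id <- array(0L, dim(mask)); id[idx] <- seq_len(N)
  row_i <- ((idx - 1L) %% nr) + 1L
  col_i <- ((idx - 1L) %/% nr) + 1L
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  sdf <- section$sdf
  th <- matrix(1, N, 4L)
  nbid <- matrix(0L, N, 4L)
  for (k in 1:4) {
    rr <- row_i + offs[[k]][1L]; cc <- col_i + offs[[k]][2L]
    inb <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncol(mask)
    lin <- ifelse(inb, (cc - 1L) * nr + rr, NA_integer_)
    nbid[, k] <- ifelse(inb, id[ifelse(inb, lin, 1L)], 0L)
    out <- nbid[, k] == 0L
    if (!is.null(sdf)) {
      phi_i <- sdf[idx]
      phi_nb <- ifelse(inb, sdf[ifelse(inb, lin, 1L)], -phi_i)
      t_ <- phi_i / (phi_i - phi_nb)
      t_[!is.finite(t_)] <- 0.5
      th[, k] <- ifelse(out, pmin(pmax(t_, 0.05), 1), 1)
    } else {
      th[, k] <- ifelse(out, 0.5, 1)
    }
  }
  ii <- jj <- integer(0); vv <- numeric(0)
  dg <- numeric(N)
  for (dim_ in 1:2) {
    k1 <- 2L * dim_ - 1L; k2 <- 2L * dim_
    dg <- dg + (2 / h^2) / (th[, k1] * th[, k2])
    for (k in c(k1, k2)) {
      tk <- th[, k]; to <- th[, if (k == k1) k2 else k1]
      has <- nbid[, k] > 0L
      w <- (2 / h^2) / (tk * (tk + to))
      ii <- c(ii, which(has)); jj <- c(jj, nbid[has, k]); vv <- c(vv, -w[has])
    }
  }
  ii <- c(ii, seq_len(N)); jj <- c(jj, seq_len(N)); vv <- c(vv, dg)
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(N, N))
  list(K = K, N = N, h = h)
}

# Complex mobility of one assembled operator at a set of frequencies.
solve_mobility <- function(op, frequencies, props, label = "section") {
  mu <- props$viscosity_mu; rho <- props$density_rho
  N <- op$N; h <- op$h
  out <- complex(length(frequencies))
  for (i in seq_along(frequencies)) {
    f <- frequencies[i]
    res <- tryCatch({
      if (f < 1e-12) {
        u <- Matrix::solve(mu * op$K, rep(1, N))
        complex(real = sum(u), imaginary = 0) * h^2
      } else {
        om <- 2 * pi * f
        A <- rbind(cbind(mu * op$K, Matrix::Diagonal(N, -om * rho)),
                   cbind(Matrix::Diagonal(N, om * rho), mu * op$K))
        u <- Matrix::solve(A, c(rep(1, N), rep(0, N)))
        complex(real = sum(u[1:N]), imaginary = sum(u[(N + 1):(2 * N)])) * h^2
      }
    }, error = function(e)
      stop("mobility solve failed at ", label, " (f = ", f, " Hz): ",
           conditionMessage(e), call. = FALSE))
    out[i] <- res
  }
  out
}

#' Oscillatory-flow mobility of a cross-section
#'
#' Solves the complex Helmholtz problem `i w rho u = G + mu Laplacian(u)`
#' with no-slip walls on the section raster (Shortley-Weller embedded
#' boundary, central differences) and returns the volumetric flow per unit
#' axial pressure gradient, `Q / G`, in (cm^3/s)/(dyn/cm^3).
#'
#' In the steady limit the mobility tends to the Poiseuille value (e.g.
#' `pi R^4 / (8 mu)` for a circular pipe).
#'
#' @param section a [cross_section()].
#' @param frequency_f frequency in Hz (>= 0); may be a vector.
#' @param props [fluid_props()].
#' @return An object of class `harmonic_mobility`: list with `frequency_f`
#'   and complex `mobility` (same length).
#' @export
solve_harmonic_mobility <- function(section, frequency_f,
                                    props = fluid_props()) {
  stopifnot(inherits(section, "cross_section"))
  if (any(frequency_f < 0)) stop("frequency must be >= 0")
  op <- assemble_lumen_operator(section)
  mob <- solve_mobility(op, frequency_f, props,
                        label = paste0("slice z = ", section$z, " mm"))
  structure(list(frequency_f = frequency_f, mobility = mob),
            class = "harmonic_mobility")
}

# --- impedance spectra ------------------------------------------------------

new_impedance_spectrum <- function(frequencies, Z, segment, source) {
  structure(list(frequencies = frequencies, Z_L = Z, segment = segment,
                 source = source),
            class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf(
    "Longitudinal impedance spectrum (%s): %d frequencies, %.3g-%.3g Hz\n",
    x$source, length(x$frequencies), min(x$frequencies), max(x$frequencies)))
  if (!anyNA(x$segment))
    cat(sprintf("  segment z = %g to %g mm\n", x$segment[1L], x$segment[2L]))
  invisible(x)
}

#' Longitudinal impedance of a canal segment at given frequencies
#'
#' Per harmonic, the pressure drop over the segment is
#' `dP(w) = Q(w) * integral dz / mobility(z, w)` (fully developed slice-wise
#' flow), so `Z_L(w)` is the trapezoidal line integral of the reciprocal
#' mobility along z. The integrand at the segment end points is obtained by
#' linear interpolation between the bracketing slices when no slice sits
#' exactly there.
#'
#' @param geometry a [canal_geometry()].
#' @param frequencies frequencies in Hz.
#' @param props [fluid_props()].
#' @param segment `c(z_start, z_end)` in mm; default `c(0, 25)`.
#' @param freq_interp_n optional integer; when smaller than
#'   `length(frequencies)`, the mobilities are solved on this many uniformly
#'   spaced frequencies spanning the same range and `Z_L` is splined onto the
#'   requested grid (the spectrum is smooth in frequency; interpolation error
#'   is ~0.1%). Intended for large batch runs.
#' @return An `impedance_spectrum` (units dyn s/cm^5).
#' @export
impedance_spectrum <- function(geometry, frequencies, props = fluid_props(),
                               segment = c(0, 25), freq_interp_n = NULL) {
  stopifnot(inherits(geometry, "canal_geometry"))
  if (length(segment) != 2L || segment[2L] <= segment[1L])
    stop("segment must be c(z_start, z_end) with z_end > z_start")
  z <- geometry$z
  if (segment[1L] < min(z) - 1e-9 || segment[2L] > max(z) + 1e-9)
    stop("segment [", segment[1L], ", ", segment[2L],
         "] mm is not covered by sections (z = ", min(z), " to ", max(z), ")")
  if (!is.null(freq_interp_n) && freq_interp_n < length(frequencies) &&
      length(frequencies) > 2L) {
    fg <- seq(min(frequencies), max(frequencies), length.out = freq_interp_n)
    sp <- impedance_spectrum(geometry, fg, props, segment)
    Z <- complex(
      real = stats::spline(fg, Re(sp$Z_L), xout = frequencies)$y,
      imaginary = stats::spline(fg, Im(sp$Z_L), xout = frequencies)$y)
    return(new_impedance_spectrum(frequencies, Z, segment, "surrogate"))
  }
  inside <- which(z >= segment[1L] - 1e-9 & z <= segment[2L] + 1e-9)
  lo <- if (z[min(inside)] > segment[1L] + 1e-9) min(inside) - 1L else NULL
  hi <- if (z[max(inside)] < segment[2L] - 1e-9) max(inside) + 1L else NULL
  used <- sort(unique(c(lo, inside, hi)))
  # reciprocal mobility per used slice and frequency; identical slices
  # (e.g. beyond the crowded region) share one solve
  g <- matrix(0i, length(used), length(frequencies))
  for (s in seq_along(used)) {
    sec <- geometry$sections[[used[s]]]
    hit <- 0L
    for (t in seq_len(s - 1L)) {
      prev <- geometry$sections[[used[t]]]
      if (identical(prev$lumen_mask, sec$lumen_mask) &&
          identical(prev$sdf, sec$sdf)) { hit <- t; break }
    }
    if (hit > 0L) { g[s, ] <- g[hit, ]; next }
    op <- assemble_lumen_operator(sec)
    g[s, ] <- 1 / solve_mobility(op, frequencies, props,
                                 label = paste0("slice z = ", sec$z, " mm"))
  }
  zu <- z[used]
  interp_at <- function(z0) {
    if (any(abs(zu - z0) < 1e-9)) return(g[which.min(abs(zu - z0)), ])
    i2 <- which(zu > z0)[1L]; i1 <- i2 - 1L
    w <- (z0 - zu[i1]) / (zu[i2] - zu[i1])
    (1 - w) * g[i1, ] + w * g[i2, ]
  }
  mid <- which(zu > segment[1L] + 1e-9 & zu < segment[2L] - 1e-9)
  nodes_z <- c(segment[1L], zu[mid], segment[2L])
  nodes_g <- rbind(interp_at(segment[1L]),
                   g[mid, , drop = FALSE],
                   interp_at(segment[2L]))
  zcm <- nodes_z / 10
  n <- length(zcm)
  wts <- (c(diff(zcm), 0) + c(0, diff(zcm))) / 2
  Z <- as.vector(wts %*% nodes_g)
  new_impedance_spectrum(frequencies, Z, segment, "surrogate")
}

#' Impedance spectrum at the cardiac harmonics of a waveform
#'
#' Evaluates [impedance_spectrum()] at the harmonic frequencies `k / T` of
#' the given waveform. By construction the result does not depend on the
#' waveform's shape or amplitude, only on its period.
#'
#' @inheritParams impedance_spectrum
#' @param waveform a [flow_waveform()] defining period and sampling.
#' @param max_harmonic highest harmonic to evaluate; default `n_samples / 2`.
#' @return An `impedance_spectrum` at the cardiac harmonics.
#' @export
pressure_drop_spectrum <- function(geometry, waveform, props = fluid_props(),
                                   segment = c(0, 25), max_harmonic = NULL) {
  stopifnot(inherits(waveform, "flow_waveform"))
  kmax <- min(max_harmonic %||% Inf, waveform$n_samples %/% 2L)
  freqs <- seq_len(kmax) / waveform$period_T
  sp <- impedance_spectrum(geometry, freqs, props, segment)
  sp$source <- "surrogate harmonics"
  sp
}

#' Steady-limit resistance of a canal segment
#'
#' The f = 0 (Poiseuille) limit of the longitudinal impedance, dyn s/cm^5.
#'
#' @inheritParams impedance_spectrum
#' @return scalar resistance.
#' @export
steady_resistance <- function(geometry, props = fluid_props(),
                              segment = c(0, 25)) {
  Re(impedance_spectrum(geometry, 0, props, segment)$Z_L)
}

#' Longitudinal impedance from pressure-drop and flow time traces
#'
#' Discrete Fourier coefficients of the pressure-drop trace divided by those
#' of the flow trace at the cardiac harmonics `k / T`. Harmonics whose flow
#' coefficient magnitude falls below `1e-8` of the largest are dropped rather
#' than divided.
#'
#' @param delta_P a [pressure_trace()] or a numeric vector of pressure drops
#'   in dyn/cm^2, sampled like the waveform.
#' @param waveform the matching [flow_waveform()].
#' @return An `impedance_spectrum` at the retained harmonics.
#' @export
longitudinal_impedance_from_traces <- function(delta_P, waveform) {
  stopifnot(inherits(waveform, "flow_waveform"))
  p <- if (inherits(delta_P, "pressure_trace")) delta_P$delta_P else delta_P
  if (inherits(delta_P, "pressure_trace") &&
      abs(delta_P$period_T - waveform$period_T) > 1e-9 * waveform$period_T)
    stop("pressure trace and waveform periods differ")
  q <- waveform$samples_Q
  if (length(p) != length(q))
    stop("pressure and flow traces have different lengths (",
         length(p), " vs ", length(q), ")")
  n <- length(q)
  P <- stats::fft(p) / n
  Q <- stats::fft(q) / n
  ks <- seq_len(n %/% 2L)
  qmag <- Mod(Q[ks + 1L])
  if (max(qmag) == 0) stop("flow trace is identically zero")
  keep <- ks[qmag >= 1e-8 * max(qmag)]
  if (!length(keep)) stop("no usable harmonics in the flow trace")
  Z <- P[keep + 1L] / Q[keep + 1L]
  new_impedance_spectrum(keep / waveform$period_T, Z, c(NA_real_, NA_real_),
                         "traces")
}

#' A pressure-drop time trace over one cardiac cycle
#'
#' @param delta_P zero-mean pressure drop samples in dyn/cm^2.
#' @param period_T period in s.
#' @param steady steady (DC) pressure-drop component, reported separately.
#' @return An object of class `pressure_trace`.
#' @export
pressure_trace <- function(delta_P, period_T, steady = 0) {
  structure(list(delta_P = as.numeric(delta_P), period_T = period_T,
                 steady = steady, n_samples = length(delta_P)),
            class = "pressure_trace")
}

#' Reconstruct the pressure-drop time trace over a segment
#'
#' Synthesises `dP(t)` from the flow waveform's Fourier coefficients and the
#' surrogate impedance at the cardiac harmonics (inverse transform), for
#' plotting alongside the flow waveform. Harmonics with negligible flow
#' content are skipped. Any steady flow component is reported separately via
#' the steady resistance.
#'
#' @inheritParams pressure_drop_spectrum
#' @return A [pressure_trace()] sampled like the waveform.
#' @export
reconstruct_pressure_trace <- function(geometry, waveform,
                                       props = fluid_props(),
                                       segment = c(0, 25)) {
  q <- waveform$samples_Q
  n <- length(q)
  Q <- stats::fft(q) / n
  ks <- seq_len(n %/% 2L)
  qmag <- Mod(Q[ks + 1L])
  Phat <- complex(length.out = n)
  if (max(qmag) > 0) {
    keep <- ks[qmag >= 1e-8 * max(qmag)]
    if (length(keep)) {
      sp <- impedance_spectrum(geometry, keep / waveform$period_T, props,
                               segment)
      Pk <- sp$Z_L * Q[keep + 1L]
      Phat[keep + 1L] <- Pk
      Phat[n - keep + 1L] <- Conj(Pk)
    }
  }
  steady <- if (abs(mean(q)) > 1e-12 * max(abs(q), 1e-300))
    steady_resistance(geometry, props, segment) * mean(q) else 0
  p <- Re(stats::fft(Phat, inverse = TRUE))
  pressure_trace(p, waveform$period_T, steady = steady)
}

# --- ILI --------------------------------------------------------------------

#' Integrated longitudinal impedance (ILI)
#'
#' Trapezoidal integral of `|Z_L(f)|` over the frequency band (default 1-8
#' Hz). The result has units of impedance times frequency, dyn/cm^5. When the
#' spectrum is only available at cardiac harmonics, `|Z_L|` is linearly
#' interpolated onto the band end points first (held constant beyond the
#' outermost harmonic).
#'
#' @param spectrum an `impedance_spectrum`.
#' @param band `c(f_lo, f_hi)` in Hz; default `c(1, 8)`.
#' @param reduction how to reduce complex Z_L before integrating: its modulus
#'   (default, consistent with the reported dyn/cm^5 unit) or its real part.
#' @param quadrature "band_integral" (default; trapezoid over the band, the
#'   only reading whose units are dyn/cm^5) or "harmonic_sum" (plain sum of
#'   the reduced Z_L over the spectrum frequencies inside the band, units
#'   dyn s/cm^5), provided because the field literature states the reduction
#'   loosely.
#' @return An object of class `ili_result` with fields `ili`, `band`,
#'   `evaluation_frequencies`.
#' @export
compute_ili <- function(spectrum, band = c(1, 8),
                        reduction = c("modulus", "real"),
                        quadrature = c("band_integral", "harmonic_sum")) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  reduction <- match.arg(reduction)
  quadrature <- match.arg(quadrature)
  if (length(band) != 2L || band[2L] <= band[1L] || band[1L] < 0)
    stop("band must be c(f_lo, f_hi) with 0 <= f_lo < f_hi")
  f <- spectrum$frequencies
  inb <- f >= band[1L] - 1e-12 & f <= band[2L] + 1e-12
  if (sum(inb) < 2L)
    stop("band [", band[1L], ", ", band[2L], "] Hz not covered; available ",
         "frequencies: ", paste(signif(f, 4), collapse = ", "))
  mag <- if (reduction == "modulus") Mod(spectrum$Z_L) else Re(spectrum$Z_L)
  if (quadrature == "harmonic_sum") {
    return(structure(list(ili = sum(mag[inb]), band = band,
                          evaluation_frequencies = f[inb],
                          reduction = reduction, quadrature = quadrature),
                     class = "ili_result"))
  }
  nodes <- sort(unique(c(band, f[inb])))
  vals <- stats::approx(f, mag, xout = nodes, rule = 2)$y
  structure(list(ili = trapz(nodes, vals), band = band,
                 evaluation_frequencies = nodes, reduction = reduction,
                 quadrature = quadrature),
            class = "ili_result")
}

#' @export
print.ili_result <- function(x, ...) {
  cat(sprintf("ILI = %.1f dyn/cm^5 over %g-%g Hz (%d nodes, %s)\n",
              x$ili, x$band[1L], x$band[2L],
              length(x$evaluation_frequencies), x$reduction))
  invisible(x)
}

#' ILI of a canal geometry (frequency-domain surrogate)
#'
#' Convenience wrapper: evaluates the impedance spectrum on a uniform grid of
#' `n_freq` points across the band and integrates `|Z_L|`.
#'
#' @inheritParams impedance_spectrum
#' @param band integration band in Hz.
#' @param n_freq number of evaluation frequencies across the band (>= 29).
#' @return An `ili_result`.
#' @export
ili <- function(geometry, props = fluid_props(), segment = c(0, 25),
                band = c(1, 8), n_freq = 29, freq_interp_n = NULL) {
  if (n_freq < 29) stop("n_freq must be at least 29 across the band")
  freqs <- seq(band[1L], band[2L], length.out = n_freq)
  sp <- impedance_spectrum(geometry, freqs, props, segment,
                           freq_interp_n = freq_interp_n)
  compute_ili(sp, band)
}

# --- I/O --------------------------------------------------------------------

#' Read a flow waveform from CSV (columns time_s, flow_cm3_per_s)
#' @param path CSV path.
#' @return A [flow_waveform()].
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "flow_cm3_per_s") %in% names(df)))
    stop("waveform CSV needs columns time_s, flow_cm3_per_s")
  dt <- diff(df$time_s)
  if (any(abs(dt - dt[1L]) > 1e-9 * dt[1L]))
    stop("waveform samples must be uniformly spaced")
  flow_waveform(df$flow_cm3_per_s, period_T = dt[1L] * nrow(df))
}

#' Write a flow waveform to CSV
#' @param waveform a [flow_waveform()].
#' @param path CSV path.
#' @export
write_waveform_csv <- function(waveform, path) {
  n <- waveform$n_samples
  utils::write.csv(data.frame(
    time_s = (seq_len(n) - 1L) * waveform$period_T / n,
    flow_cm3_per_s = waveform$samples_Q), path, row.names = FALSE)
  invisible(path)
}

#' Write an impedance spectrum (and optional ILI) to JSON and CSV
#'
#' @param spectrum an `impedance_spectrum`.
#' @param path output path without extension; `.json` and `.csv` twins are
#'   written.
#' @param ili_result optional [compute_ili()] result to embed.
#' @export
write_spectrum <- function(spectrum, path, ili_result = NULL) {
  obj <- list(segment_mm = spectrum$segment,
              frequencies_hz = spectrum$frequencies,
              zl_real = Re(spectrum$Z_L), zl_imag = Im(spectrum$Z_L))
  if (!is.null(ili_result)) obj$ili_dyn_cm5 <- ili_result$ili
  jsonlite::write_json(obj, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(data.frame(frequency_hz = spectrum$frequencies,
                              zl_real = Re(spectrum$Z_L),
                              zl_imag = Im(spectrum$Z_L),
                              zl_mod = Mod(spectrum$Z_L)),
                   paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
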