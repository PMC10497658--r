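props <- fluid_props()

test_that("mobility reaches the Poiseuille limit as f -> 0", {
  pipe <- rasterize_annulus(0.5, 0, pixel_spacing = 0.5 / 32 * 10)
  mob <- solve_harmonic_mobility(pipe, 1e-4, props)
  pois <- pi * 0.5^4 / (8 * 0.01)
  expect_lt(abs(mob$mobility - pois) / pois, 0.01)
  expect_gt(Re(mob$mobility), 0)
})

test_that("mobility matches the Womersley closed form at alpha = 10", {
  R <- 0.5
  f <- 10^2 * 0.01 / (R^2 * 1 * 2 * pi)
  pipe <- rasterize_annulus(R, 0, pixel_spacing = R / 48 * 10)
  mob <- solve_harmonic_mobility(pipe, f, props)$mobility
  ex <- womersley_pipe_mobility(R, f)
  expect_lt(abs(mob - ex) / abs(ex), 0.02)
})

test_that("annulus mobility matches the 1D radial BVP oracle", {
  Ro <- 0.8; Ri <- 0.5
  ann <- rasterize_annulus(Ro, Ri, 0.15)
  for (alpha in c(1, 30)) {
    f <- alpha^2 * 0.01 / (Ro^2 * 2 * pi)
    mob <- solve_harmonic_mobility(ann, f, props)$mobility
    ex <- annulus_radial_mobility(Ro, Ri, f)
    expect_lt(abs(mob - ex) / abs(ex), 0.02)
  }
})

test_that("mobility solver converges at second order on the pipe", {
  R <- 0.5
  f <- 10^2 * 0.01 / (R^2 * 2 * pi)
  ex <- womersley_pipe_mobility(R, f)
  errs <- sapply(c(16, 32, 64), function(res) {
    m <- solve_harmonic_mobility(rasterize_annulus(R, 0, R / res * 10), f,
                                 props)$mobility
    abs(m - ex) / abs(ex)
  })
  expect_true(all(diff(errs) < 0))
  order_est <- log(errs[1] / errs[3]) / log(4)
  expect_gt(order_est, 1.5)
})

test_that("steady-limit Z_L matches Poiseuille closed forms", {
  mkgeo <- function(Ro, Ri, px) canal_geometry(lapply(
    c(0, 12.5, 25), function(z) rasterize_annulus(Ro, Ri, px, z = z)))
  Zp <- steady_resistance(mkgeo(0.5, 0, 0.15))
  expect_lt(abs(Zp - pipe_poiseuille_resistance(0.5, 2.5)) /
              pipe_poiseuille_resistance(0.5, 2.5), 0.01)
  Za <- steady_resistance(mkgeo(0.8, 0.5, 0.1))
  exa <- annulus_poiseuille_resistance(0.8, 0.5, 2.5)
  expect_lt(abs(Za - exa) / exa, 0.01)
})

test_that("Z_L is additive over contiguous segments", {
  geo <- canal_geometry(c(
    lapply(c(0, 6, 12.5), function(z) rasterize_annulus(0.5, 0, 0.2, z = z)),
    lapply(c(13.5, 19, 25), function(z) rasterize_annulus(0.35, 0, 0.2, z = z))))
  f <- c(1, 4, 8)
  Ztot <- impedance_spectrum(geo, f, props, segment = c(0, 25))$Z_L
  Z1 <- impedance_spectrum(geo, f, props, segment = c(0, 13))$Z_L
  Z2 <- impedance_spectrum(geo, f, props, segment = c(13, 25))$Z_L
  expect_equal(Ztot, Z1 + Z2, tolerance = 1e-12)
})

test_that("narrowing the canal raises impedance; steady part scales as s^-4", {
  f <- c(1, 4, 8)
  g1 <- canal_geometry(lapply(c(0, 12.5, 25), function(z)
    rasterize_annulus(0.5, 0, 0.1, z = z)))
  g2 <- canal_geometry(lapply(c(0, 12.5, 25), function(z)
    rasterize_annulus(0.4, 0, 0.1, z = z)))
  Z1 <- impedance_spectrum(g1, f, props)$Z_L
  Z2 <- impedance_spectrum(g2, f, props)$Z_L
  expect_true(all(Mod(Z2) > Mod(Z1)))
  r0 <- steady_resistance(g2) / steady_resistance(g1)
  expect_lt(abs(r0 - 0.8^-4) / 0.8^-4, 0.03)
})

test_that("trace-based Z_L recovers proportional and inertive relations", {
  w <- make_waveform(n_samples = 64)
  # dP = R0 Q -> Z = R0 at every retained harmonic
  sp <- longitudinal_impedance_from_traces(25 * w$samples_Q, w)
  expect_true(all(abs(sp$Z_L - 25) < 1e-9))
  # single-harmonic Q with dP = L dQ/dt -> purely imaginary, 2 pi f L
  n <- 64; T <- w$period_T
  t <- (seq_len(n) - 1) * T / n
  q <- cos(2 * pi * t / T)
  Leff <- 3.7
  dp <- -Leff * 2 * pi / T * sin(2 * pi * t / T)
  spi <- longitudinal_impedance_from_traces(dp, flow_waveform(q, T))
  k1 <- which.min(abs(spi$frequencies - 1 / T))
  expect_lt(abs(Re(spi$Z_L[k1])), 1e-9)
  expect_equal(Mod(spi$Z_L[k1]), 2 * pi / T * Leff, tolerance = 1e-9)
})

test_that("time-domain round trip reproduces the generating spectrum", {
  geo <- canal_geometry(lapply(c(0, 12.5, 25), function(z)
    rasterize_annulus(0.8, 0.5, 0.2, z = z)))
  # waveform with content at harmonics 1-6
  n <- 100; T <- 60 / 86.3
  t <- (seq_len(n) - 1) / n
  q <- rowSums(sapply(1:6, function(k)
    (0.8^k) * cos(2 * pi * k * t - 0.5 * k)))
  w <- flow_waveform(2.5 * q / max(q), T)
  tr <- reconstruct_pressure_trace(geo, w, props)
  expect_true(is.numeric(tr$delta_P))  # synthesis is real
  back <- longitudinal_impedance_from_traces(tr, w)
  direct <- pressure_drop_spectrum(geo, w, props, max_harmonic = 6)
  i6 <- match(round(direct$frequencies, 9), round(back$frequencies, 9))
  relerr <- Mod(back$Z_L[i6] - direct$Z_L) / Mod(direct$Z_L)
  expect_lt(max(relerr), 0.005)
})

test_that("zero waveform reconstructs a zero trace and errors in Eq. ratios", {
  geo <- canal_geometry(lapply(c(0, 25), function(z)
    rasterize_annulus(0.5, 0, 0.3, z = z)))
  w0 <- flow_waveform(rep(0, 32))
  expect_equal(max(abs(reconstruct_pressure_trace(geo, w0, props)$delta_P)), 0)
  expect_error(longitudinal_impedance_from_traces(rep(0, 32), w0), "zero")
  expect_error(longitudinal_impedance_from_traces(rep(1, 16),
                                                  make_waveform(n_samples = 32)),
               "lengths")
})

test_that("ILI quadrature identities hold exactly", {
  mk_spec <- function(f, Z) structure(
    list(frequencies = f, Z_L = Z, segment = c(NA_real_, NA_real_),
         source = "constructed"), class = "impedance_spectrum")
  f <- seq(1, 8, length.out = 29)
  expect_equal(compute_ili(mk_spec(f, complex(real = rep(3.2, 29))))$ili,
               7 * 3.2, tolerance = 1e-12)
  expect_equal(compute_ili(mk_spec(f, complex(real = f)))$ili, 31.5,
               tolerance = 1e-12)
  # band not covered -> informative error
  expect_error(compute_ili(mk_spec(c(10, 12), c(1 + 0i, 1 + 0i))),
               "not covered")
  # the harmonic-sum alternative is a plain sum over in-band frequencies
  hs <- compute_ili(mk_spec(f, complex(real = f)),
                    quadrature = "harmonic_sum")
  expect_equal(hs$ili, sum(f), tolerance = 1e-12)
  # real-part reduction
  zr <- complex(real = rep(2, 29), imaginary = rep(5, 29))
  expect_equal(compute_ili(mk_spec(f, zr), reduction = "real")$ili, 14,
               tolerance = 1e-12)
})

test_that("harmonic-only spectra are interpolated onto the band edges", {
  # |Z| linear in f: interpolation is exact, integral is the trapezoid
  f <- (1:6) * 1.4383
  mk <- structure(list(frequencies = f, Z_L = complex(real = 2 * f),
                       segment = c(NA_real_, NA_real_), source = "traces"),
                  class = "impedance_spectrum")
  # |Z| = 2f held constant below the first harmonic (rule = 2 extension)
  f1 <- f[1]
  expected <- (f1 - 1) * 2 * f1 + (64 - f1^2)  # rectangle + exact trapezoid
  expect_equal(compute_ili(mk)$ili, expected, tolerance = 1e-10)
})

test_that("surrogate ILI is independent of the driving waveform", {
  geo <- canal_geometry(lapply(c(0, 12.5, 25), function(z)
    rasterize_annulus(0.8, 0.55, 0.25, z = z)))
  ilis <- sapply(list(make_waveform(peak_flow_cm3_s = 1),
                      make_waveform(peak_flow_cm3_s = 5, shape_seed = 7)),
                 function(w) {
    tr <- reconstruct_pressure_trace(geo, w, props)
    compute_ili(longitudinal_impedance_from_traces(tr, w))$ili
  })
  expect_lt(abs(diff(ilis)) / ilis[1], 0.005)
})

test_that("invalid segments and frequencies are rejected", {
  geo <- canal_geometry(lapply(c(0, 25), function(z)
    rasterize_annulus(0.5, 0, 0.4, z = z)))
  expect_error(impedance_spectrum(geo, 1, props, segment = c(0, 40)),
               "not covered")
  expect_error(impedance_spectrum(geo, 1, props, segment = c(10, 5)),
               "z_end")
  expect_error(solve_harmonic_mobility(geo$sections[[1]], -1), ">= 0")
  expect_error(ili(geo, n_freq = 10), "29")
  expect_error(flow_waveform(1:8), "16")
})
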