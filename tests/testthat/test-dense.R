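# helpers to build small series/masks in code
square_mask <- function(n = 32, px = 1, lo = 8, hi = 25) {
  lab <- matrix(0L, n, n)
  lab[lo:hi, lo:hi] <- 1L
  region_mask(lab, px, c(cerebellum = 1L))
}

series_from_phase <- function(ph, px = 1, ke = 0.6) {
  arr <- array(ph, c(nrow(ph), ncol(ph), 2L))
  dense_series(array(100, dim(arr)), arr, arr, pixel_size = px, ke = ke)
}

test_that("in-range smooth phase fields pass unwrapping unchanged", {
  msk <- square_mask()
  ph <- matrix(0, 32, 32)
  ph[8:25, 8:25] <- outer(seq(-1, 1, length.out = 18),
                          seq(-1, 1, length.out = 18), function(a, b) a + b)
  s <- series_from_phase(ph)
  u <- unwrap_phase(s, msk)
  expect_identical(u$phase_ap, s$phase_ap)
  expect_true(u$unwrapped)
})

test_that("a 3-pi phase ramp is unwrapped to the generating ramp", {
  msk <- square_mask()
  truth <- matrix(0, 32, 32)
  truth[8:25, 8:25] <- matrix(rep(seq(0, 3 * pi, length.out = 18), each = 18),
                              18, 18)
  wrapped <- (truth + pi) %% (2 * pi) - pi
  s <- series_from_phase(wrapped)
  u <- unwrap_phase(s, msk)
  reg <- msk$labels == 1L
  resid <- u$phase_ap[, , 1][reg] - truth[reg]
  offset <- 2 * pi * round(stats::median(resid) / (2 * pi))
  expect_lt(max(abs(resid - offset)), 1e-6)
})

test_that("noisy ramps unwrap without residual 2-pi jumps", {
  set.seed(42)
  msk <- square_mask()
  truth <- matrix(0, 32, 32)
  truth[8:25, 8:25] <- matrix(rep(seq(0, 3 * pi, length.out = 18), each = 18),
                              18, 18) +
    stats::rnorm(18 * 18, 0, 0.2)
  wrapped <- (truth + pi) %% (2 * pi) - pi
  u <- unwrap_phase(series_from_phase(wrapped), msk)
  reg <- msk$labels == 1L
  resid <- u$phase_ap[, , 1][reg] - truth[reg]
  resid <- resid - 2 * pi * round(stats::median(resid) / (2 * pi))
  expect_lt(max(abs(resid)), pi)  # no 2-pi magnitude jumps survive
})

test_that("phase decodes to displacement via u = phi / (2 pi ke)", {
  ph <- matrix(2 * pi * 0.6 * 0.1, 20, 20)  # encodes 0.1 mm
  maps <- phase_to_displacement(series_from_phase(ph))
  expect_equal(maps$ap[1, 1, 1], 100, tolerance = 1e-9)
  mp <- phase_to_displacement(series_from_phase(matrix(pi, 20, 20)))
  expect_equal(mp$ap[1, 1, 1], 1000 / (2 * 0.6), tolerance = 1e-9)
  expect_error(dense_series(array(1, c(4, 4, 1)), array(0, c(4, 4, 1)),
                            array(0, c(4, 4, 1)), ke = 0), "ke")
})

test_that("displacement filter preserves DC and total mass", {
  k <- displacement_filter_kernel()
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_length(k, 17)
  # uniform field unchanged
  uni <- structure(list(ap = array(200, c(40, 40, 2)),
                        cc = array(200, c(40, 40, 2)),
                        validity = matrix(TRUE, 40, 40), pixel_size = 0.9,
                        frame_interval = 34), class = "displacement_maps")
  fu <- filter_displacement(uni)
  expect_lt(max(abs(fu$ap - 200)), 0.1)
  # interior impulse: peak scaled by the kernel centre weight, mass kept
  imp <- uni; imp$ap[] <- 0; imp$cc[] <- 0
  imp$ap[20, 20, 1] <- 1000
  fi <- filter_displacement(imp)
  centre_w <- k[9]^2
  expect_equal(max(fi$ap[, , 1]), 1000 * centre_w, tolerance = 1e-9)
  expect_lt(abs(sum(fi$ap[, , 1]) - 1000) / 1000, 0.005)
})

test_that("filtering reduces noise and never raises a non-negative maximum", {
  set.seed(7)
  truth <- outer(1:40, 1:40, function(i, j)
    150 * exp(-((i - 20)^2 + (j - 20)^2) / 200))
  noisy <- truth + matrix(stats::rnorm(1600, 0, 50), 40, 40)
  mk <- function(m) structure(list(
    ap = array(m, c(40, 40, 1)), cc = array(0, c(40, 40, 1)),
    validity = matrix(TRUE, 40, 40), pixel_size = 0.9, frame_interval = 34),
    class = "displacement_maps")
  f <- filter_displacement(mk(noisy))
  rms_before <- sqrt(mean((noisy - truth)^2))
  rms_after <- sqrt(mean((f$ap[, , 1] - truth)^2))
  expect_lt(rms_after, rms_before)
  # max never increases for non-negative fields
  pos <- abs(noisy)
  fp <- filter_displacement(mk(pos))
  expect_lte(max(fp$ap), max(pos))
  small <- structure(list(ap = array(0, c(5, 5, 1)), cc = array(0, c(5, 5, 1)),
                          validity = matrix(TRUE, 5, 5), pixel_size = 0.9,
                          frame_interval = 34), class = "displacement_maps")
  expect_error(filter_displacement(small), "smaller")
  expect_error(displacement_filter_kernel(cutoff = 1.2), "cutoff")
  expect_error(displacement_filter_kernel(order = 15), "even")
})

test_that("uniform oscillating fields summarise to their peak", {
  n <- 40
  lab <- matrix(0L, n, n); lab[8:32, 8:32] <- 1L
  msk <- erode_region(region_mask(lab, 0.9, c(cerebellum = 1L)), 2)
  w <- c(0.2, 1, 0.6)
  maps <- structure(list(
    ap = array(rep(250 / sqrt(2) * rep(w, each = n * n)), c(n, n, 3)),
    cc = array(rep(250 / sqrt(2) * rep(w, each = n * n)), c(n, n, 3)),
    validity = matrix(TRUE, n, n), pixel_size = 0.9, frame_interval = 34),
    class = "displacement_maps")
  s <- summarize_region(maps, msk, "cerebellum")
  expect_equal(s$displacement_um, 250, tolerance = 1e-9)
  expect_equal(s$frame_of_peak, 2L)
})

test_that("a Gaussian bump summarises to its analytic disc average", {
  n <- 64; px <- 0.9
  lab <- matrix(0L, n, n); lab[5:60, 5:60] <- 1L
  msk <- erode_region(region_mask(lab, px, c(cerebellum = 1L)), 2)
  xs <- (seq_len(n) - 32) * px
  sig <- 6; peak <- 400
  bump <- peak * exp(-(outer(xs^2, xs^2, "+")) / (2 * sig^2))
  maps <- structure(list(ap = array(bump, c(n, n, 1)),
                         cc = array(0, c(n, n, 1)),
                         validity = matrix(TRUE, n, n), pixel_size = px,
                         frame_interval = 34), class = "displacement_maps")
  s <- summarize_region(maps, msk, "cerebellum")
  a <- sqrt(30 / pi)
  analytic <- peak * (2 * sig^2 / a^2) * (1 - exp(-a^2 / (2 * sig^2)))
  expect_lt(abs(s$displacement_um - analytic) / analytic, 0.02)
  expect_gt(s$displacement_um, 350)
  expect_lt(s$displacement_um, 400)
  # ROI is centred on the bump
  expect_lt(max(abs(s$roi_center - 32)), 2)
})

test_that("the ROI shifts to fit inside the region or errors out", {
  n <- 40; px <- 0.9
  lab <- matrix(0L, n, n); lab[10:30, 10:30] <- 1L
  msk <- erode_region(region_mask(lab, px, c(cerebellum = 1L)), 2)
  # hot pixel at the region corner: ROI must shift inward
  fld <- matrix(0, n, n); fld[12, 12] <- 300
  maps <- structure(list(ap = array(fld, c(n, n, 1)),
                         cc = array(0, c(n, n, 1)),
                         validity = matrix(TRUE, n, n), pixel_size = px,
                         frame_interval = 34), class = "displacement_maps")
  s <- summarize_region(maps, msk, "cerebellum")
  reg <- msk$labels == 1L
  ro <- s$roi_center
  expect_true(reg[ro[1], ro[2]])
  # region too small for the ROI
  lab2 <- matrix(0L, n, n); lab2[18:22, 18:22] <- 1L
  msk2 <- region_mask(lab2, px, c(cerebellum = 1L), eroded = TRUE)
  expect_error(summarize_region(maps, msk2, "cerebellum"), "does not fit")
})

test_that("summaries are invariant to a temporal phase shift of the motion", {
  n <- 40
  lab <- matrix(0L, n, n); lab[8:32, 8:32] <- 1L
  msk <- erode_region(region_mask(lab, 0.9, c(cerebellum = 1L)), 2)
  w <- exp(-((1:8 / 8 - 0.4) / 0.2)^2)
  base <- outer(1:n, 1:n, function(i, j) 100 + i + j)
  mk <- function(wv) structure(list(
    ap = array(outer(c(base), wv), c(n, n, 8)),
    cc = array(0, c(n, n, 8)),
    validity = matrix(TRUE, n, n), pixel_size = 0.9, frame_interval = 34),
    class = "displacement_maps")
  s1 <- summarize_region(mk(w), msk, "cerebellum")
  s2 <- summarize_region(mk(c(w[4:8], w[1:3])), msk, "cerebellum")
  expect_equal(s1$displacement_um, s2$displacement_um, tolerance = 1e-12)
})

test_that("erosion arithmetic and degenerate regions behave as specified", {
  n <- 20
  lab <- matrix(0L, n, n); lab[6:15, 6:15] <- 1L  # 10x10 square
  msk <- region_mask(lab, 1, c(cerebellum = 1L))
  expect_identical(erode_region(msk, 0)$labels, msk$labels)
  e2 <- erode_region(msk, 2)
  expect_equal(sum(e2$labels == 1L), 36)  # 6x6 survives
  expect_true(e2$eroded)
  # 3-voxel-wide annular region vanishes under width-2 erosion
  ring <- matrix(0L, 30, 30)
  d <- sqrt(outer((1:30 - 15.5)^2, (1:30 - 15.5)^2, "+"))
  ring[d >= 8 & d < 11] <- 1L
  expect_error(erode_region(region_mask(ring, 1, c(cerebellum = 1L)), 2),
               "vanished")
})

test_that("encode-decode round trip is exact without noise", {
  ph <- make_dense_phantom(peak_displacement = 100, pattern = "uniform",
                           snr = Inf)
  out <- dense_pipeline(ph$series, ph$mask)
  expect_lt(abs(out$summaries$cerebellum$displacement_um - 100), 1e-3)
  # per-pixel recovery (decode only, no filtering) better than 1 um
  bump <- make_dense_phantom(peak_displacement = 300, snr = Inf)
  me <- erode_region(bump$mask, 2)
  maps <- phase_to_displacement(unwrap_phase(bump$series, me))
  expect_lt(max(abs(maps$ap - bump$truth_maps$ap)), 1)
  expect_lt(max(abs(maps$cc - bump$truth_maps$cc)), 1)
})

test_that("noisy phantoms recover the ROI summary within the accuracy bound", {
  errs <- sapply(1:2, function(s) {
    p <- make_dense_phantom(seed = s)
    o <- dense_pipeline(p$series, p$mask)
    o$summaries$cerebellum$displacement_um -
      p$truth_summary$cerebellum$displacement_um
  })
  expect_lt(max(abs(errs)), 13)
})

test_that("warnings and errors guard the region plumbing", {
  n <- 20
  lab <- matrix(0L, n, n); lab[6:15, 6:15] <- 1L
  msk <- region_mask(lab, 1, c(cerebellum = 1L))
  maps <- structure(list(ap = array(1, c(n, n, 1)), cc = array(0, c(n, n, 1)),
                         validity = matrix(TRUE, n, n), pixel_size = 1,
                         frame_interval = 34), class = "displacement_maps")
  expect_warning(summarize_region(maps, msk, "cerebellum", roi_area = 4),
                 "not eroded")
  expect_error(summarize_region(maps, msk, "thalamus"), "not present")
  tiny <- matrix(0L, 10, 10); tiny[5, 5] <- 1L
  s <- series_from_phase(matrix(0.1, 10, 10))
  expect_warning(unwrap_phase(s, region_mask(tiny, 1, c(cerebellum = 1L))),
                 "smaller than 4")
})
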