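test_that("disc and annulus metrics match circle identities", {
  # R = 1 cm disc at 0.02 cm/pixel
  disc <- rasterize_annulus(1.0, 0, pixel_spacing = 0.2)
  m <- section_metrics(disc)
  expect_lt(abs(m$area_cm2 - pi) / pi, 0.02)
  expect_lt(abs(m$perimeter_cm - 2 * pi) / (2 * pi), 0.02)
  expect_lt(abs(m$dh_cm - 2) / 2, 0.02)
  # same raster stripped to a pure binary mask (no sub-pixel boundary info)
  mb <- section_metrics(as_binary_section(disc))
  expect_lt(abs(mb$area_cm2 - pi) / pi, 0.02)
  expect_lt(abs(mb$perimeter_cm - 2 * pi) / (2 * pi), 0.02)
  # concentric annulus: D_H = 2 (Ro - Ri)
  ann <- rasterize_annulus(0.8, 0.5, 0.2)
  ma <- section_metrics(ann)
  expect_lt(abs(ma$dh_cm - 0.6) / 0.6, 0.02)
  # D_H = 4A/P holds by construction
  expect_equal(ma$dh_cm, 4 * ma$area_cm2 / ma$perimeter_cm)
})

test_that("eccentric annulus metrics converge to the polygon oracle", {
  oracle <- annulus_polygon_metrics(0.8, 0.5, ecc = 0.1)
  errs <- sapply(c(0.4, 0.1), function(px) {
    m <- section_metrics(rasterize_annulus(0.8, 0.5, px, eccentricity = 0.1))
    c(a = abs(m$area_cm2 - oracle$area) / oracle$area,
      p = abs(m$perimeter_cm - oracle$perimeter) / oracle$perimeter)
  })
  expect_lt(errs["a", 2], errs["a", 1])  # refinement improves
  expect_lt(errs["a", 2], 0.01)
  expect_lt(errs["p", 2], 0.01)
})

test_that("metrics scale correctly with linear dimension", {
  # same raster, doubled pixel spacing: exact scaling
  d1 <- rasterize_annulus(1.0, 0, 0.4)
  d2 <- cross_section(d1$lumen_mask, d1$pixel_spacing * 2, z = 0)
  m1 <- section_metrics(as_binary_section(d1)); m2 <- section_metrics(d2)
  expect_equal(m2$area_cm2 / m1$area_cm2, 4, tolerance = 1e-10)
  expect_equal(m2$perimeter_cm / m1$perimeter_cm, 2, tolerance = 1e-10)
  # physically rescaled disc at fixed spacing: within raster tolerance
  s1 <- section_metrics(rasterize_annulus(0.5, 0, 0.2))
  s2 <- section_metrics(rasterize_annulus(1.0, 0, 0.2))
  expect_lt(abs(s2$area_cm2 / s1$area_cm2 - 4) / 4, 0.02)
  expect_lt(abs(s2$perimeter_cm / s1$perimeter_cm - 2) / 2, 0.02)
  expect_lt(abs(s2$dh_cm / s1$dh_cm - 2) / 2, 0.02)
})

test_that("metrics are invariant to translation and 90-degree rotation", {
  disc <- rasterize_annulus(0.6, 0, 0.4)
  mask <- disc$lumen_mask
  m0 <- section_metrics(cross_section(mask, 0.4, 0))
  # translate by padding two background rows/cols on one side
  shifted <- rbind(matrix(FALSE, 2, ncol(mask)), mask)
  shifted <- cbind(shifted, matrix(FALSE, nrow(shifted), 3))
  mt <- section_metrics(cross_section(shifted, 0.4, 0))
  expect_equal(mt$area_cm2, m0$area_cm2, tolerance = 1e-12)
  expect_equal(mt$perimeter_cm, m0$perimeter_cm, tolerance = 1e-9)
  # 90-degree rotation
  rot <- t(mask[nrow(mask):1, ])
  mr <- section_metrics(cross_section(rot, 0.4, 0))
  expect_equal(mr$area_cm2, m0$area_cm2, tolerance = 1e-12)
  expect_equal(mr$perimeter_cm, m0$perimeter_cm, tolerance = 1e-9)
})

test_that("area and perimeter errors shrink under grid refinement", {
  # coarse-to-moderate resolutions, where discretization error dominates
  # discretization error measured free of grid-alignment luck: averaged over
  # four fixed sub-pixel centre offsets at each resolution
  mkoff <- function(R, px_mm, ox, oy) {
    px <- px_mm / 10
    n <- 2L * ceiling((R + 3 * px) / px) + 1L
    xs <- (seq_len(n) - (n + 1) / 2) * px
    X <- matrix(xs, n, n) + ox * px
    Y <- t(matrix(xs, n, n)) + oy * px
    sdf <- R - sqrt(X^2 + Y^2)
    cov <- matrix(pmin(1, pmax(0, 0.5 + sdf / px)), n, n)
    cross_section(sdf >= 0, px_mm, 0, sdf = matrix(sdf * 10, n, n),
                  coverage = cov)
  }
  offs <- list(c(0.13, 0.37), c(0.41, 0.11), c(0.29, 0.23), c(0.07, 0.43))
  errs <- sapply(c(2.5, 1.25, 0.625, 0.3125), function(px) {
    rowMeans(sapply(offs, function(o) {
      m <- section_metrics(mkoff(1.0, px, o[1], o[2]))
      c(a = abs(m$area_cm2 - pi) / pi,
        p = abs(m$perimeter_cm - 2 * pi) / (2 * pi))
    }))
  })
  expect_true(all(diff(errs["a", ]) < 0))
  expect_true(all(diff(errs["p", ]) < 0))
})

test_that("degenerate masks are rejected", {
  expect_error(cross_section(matrix(FALSE, 8, 8), 1, 0), "empty")
  border <- matrix(TRUE, 8, 8)
  expect_error(cross_section(border, 1, 0), "border")
  tiny <- matrix(FALSE, 8, 8); tiny[4:5, 4:5] <- TRUE
  expect_error(cross_section(tiny, 1, 0), "10")
  expect_error(cross_section(matrix(TRUE, 4, 4), -1, 0), "pixel_spacing")
})

test_that("small disconnected fragments are dropped with a warning", {
  m <- matrix(FALSE, 40, 40)
  m[10:25, 10:25] <- TRUE   # main component
  m[32:33, 32:33] <- TRUE   # 4-pixel debris
  expect_warning(s <- cross_section(m, 1, 0), "fragment")
  expect_equal(sum(s$lumen_mask), 16 * 16)
  # two genuine components are retained
  m2 <- matrix(FALSE, 60, 60)
  m2[10:25, 10:25] <- TRUE
  m2[35:50, 35:50] <- TRUE
  expect_warning(s2 <- cross_section(m2, 1, 0), "disjoint")
  expect_equal(sum(s2$lumen_mask), 2 * 16 * 16)
})

test_that("Reynolds number follows Re = 4 rho Q / (pi mu D_H)", {
  met <- structure(list(area_cm2 = pi / 4, perimeter_cm = pi, dh_cm = 1,
                        n_pixels = 100L), class = "section_metrics")
  expect_equal(reynolds_number(10, fluid_props(), met), 4000 / pi)
  expect_equal(reynolds_number(0, fluid_props(), met), 0)
  expect_error(reynolds_number(-1, fluid_props(), met), ">= 0")
  bad <- met; bad$dh_cm <- 0
  expect_error(reynolds_number(1, fluid_props(), bad), "positive")
  # hand-recomputed value for a synthetic annulus with the default waveform
  ann <- rasterize_annulus(0.9, 0.6, 0.2)
  ma <- section_metrics(ann)
  q_peak <- max(make_waveform()$samples_Q)
  expect_equal(reynolds_number(q_peak, fluid_props(), ma),
               4 * 1.0 * q_peak / (pi * 0.01 * ma$dh_cm))
})

test_that("canal geometry enforces slice ordering and coverage", {
  mk <- function(z) rasterize_annulus(0.8, 0.5, 1, z = z)
  expect_error(canal_geometry(list(mk(0), mk(10))), "25")
  expect_error(canal_geometry(list(mk(5), mk(30))), "foramen magnum")
  expect_error(canal_geometry(list(mk(0), mk(10), mk(10), mk(30))),
               "increasing")
  g <- canal_geometry(list(mk(0), mk(12), mk(30)))
  df <- as.data.frame(g)
  expect_named(df, c("z_mm", "area_cm2", "perimeter_cm", "dh_cm"))
  expect_equal(df$z_mm, c(0, 12, 30))
})

test_that("fluid properties default to water at body temperature", {
  p <- fluid_props()
  expect_equal(p$density_rho, 1.0)
  expect_equal(p$viscosity_mu, 0.01)
  expect_error(fluid_props(-1, 0.01), "positive")
  expect_error(fluid_props(1, 0), "positive")
})
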