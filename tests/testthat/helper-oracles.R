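# Independent oracles used to check the package's numerics. These are kept
# deliberately separate from the implementation paths they validate:
# closed-form Bessel solutions, a 1D radial boundary-value solver, polygon
# geometry, and brute-force statistics formulas.

# trapezoid rule (local copy, independent of the package internals)
trapz_o <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

# --- polygon oracle ---------------------------------------------------------

# area (shoelace) and perimeter of a closed polygon
polygon_metrics <- function(x, y) {
  n <- length(x)
  a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  p <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  list(area = a, perimeter = p)
}

# high-resolution polygon representation of an eccentric annulus
annulus_polygon_metrics <- function(Ro, Ri, ecc = 0, n_vertices = 1e4) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-1]
  outer <- polygon_metrics(Ro * cos(th), Ro * sin(th))
  inner <- polygon_metrics(ecc + Ri * cos(th), Ri * sin(th))
  list(area = outer$area - inner$area,
       perimeter = outer$perimeter + inner$perimeter)
}

# --- Womersley closed form --------------------------------------------------

# Bessel J_nu of complex argument by power series (adequate for |z| < ~30)
besselJ_complex <- function(z, nu) {
  s <- 0 + 0i
  term <- (z / 2)^nu / gamma(nu + 1)
  k <- 0
  repeat {
    s <- s + term
    k <- k + 1
    term <- term * (-(z / 2)^2) / (k * (k + nu))
    if (abs(term) < 1e-18 * max(1, abs(s)) || k > 400) break
  }
  s
}

# closed-form mobility (flow per unit pressure gradient) of a circular pipe
# in fully developed oscillatory flow
womersley_pipe_mobility <- function(R, f, rho = 1, mu = 0.01) {
  if (f < 1e-12) return(pi * R^4 / (8 * mu) + 0i)
  om <- 2 * pi * f
  alpha <- R * sqrt(om * rho / mu)
  lam <- complex(modulus = alpha, argument = 3 * pi / 4)  # i^(3/2) alpha
  (pi * R^2 / (1i * om * rho)) *
    (1 - 2 * besselJ_complex(lam, 1) / (lam * besselJ_complex(lam, 0)))
}

# --- radial two-point BVP oracle for the concentric annulus ----------------

# solves i w rho u = 1 + mu (u'' + u'/r) on [Ri, Ro], u = 0 at both walls,
# by central differences + complex Thomas algorithm; returns the mobility
annulus_radial_mobility <- function(Ro, Ri, f, rho = 1, mu = 0.01, n = 3000) {
  r <- seq(Ri, Ro, length.out = n + 2)
  h <- r[2] - r[1]
  ri <- r[2:(n + 1)]
  om <- 2 * pi * f
  a <- mu / h^2 - mu / (2 * h * ri)
  b <- rep(-2 * mu / h^2 - 1i * om * rho, n)
  cc <- mu / h^2 + mu / (2 * h * ri)
  d <- rep(-1 + 0i, n)
  cp <- dp <- complex(n)
  cp[1] <- cc[1] / b[1]; dp[1] <- d[1] / b[1]
  for (i in 2:n) {
    m <- b[i] - a[i] * cp[i - 1]
    cp[i] <- cc[i] / m
    dp[i] <- (d[i] - a[i] * dp[i - 1]) / m
  }
  u <- complex(n)
  u[n] <- dp[n]
  for (i in (n - 1):1) u[i] <- dp[i] - cp[i] * u[i + 1]
  sum(u * ri) * h * 2 * pi
}

# steady annular Poiseuille resistance of a segment of length L (cm)
annulus_poiseuille_resistance <- function(Ro, Ri, L, mu = 0.01) {
  8 * mu * L / (pi * (Ro^4 - Ri^4 - (Ro^2 - Ri^2)^2 / log(Ro / Ri)))
}

# steady circular-pipe Poiseuille resistance
pipe_poiseuille_resistance <- function(R, L, mu = 0.01) {
  8 * mu * L / (pi * R^4)
}

# 1D-radial-oracle ILI of a crowded annular canal (same gap profile as
# make_geometry's plateau), at high frequency resolution
radial_oracle_ili <- function(Ro, Ri, crowding, band = c(1, 8), nz = 26,
                              n_freq = 290, profile = "plateau") {
  zs <- seq(0, 2.5, length.out = nz)  # cm
  ramp <- if (profile == "plateau") ifelse(zs <= 1, 1, pmax(0, (2.5 - zs) / 1.5))
          else pmax(0, 1 - zs / 2.5)
  g0 <- Ro - Ri
  fs <- seq(band[1], band[2], length.out = n_freq)
  mags <- vapply(fs, function(f) {
    ginv <- vapply(seq_along(zs), function(i) {
      gap <- g0 * (1 - crowding * ramp[i])
      1 / annulus_radial_mobility(Ro, Ro - gap, f, n = 1000)
    }, complex(1))
    Mod(trapz_o(zs, ginv))
  }, numeric(1))
  trapz_o(fs, mags)
}

# --- statistics oracles -----------------------------------------------------

pearson_bruteforce <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

welch_bruteforce <- function(a, b) {
  v1 <- var(a) / length(a); v2 <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# strip sub-pixel information from a section, leaving the raw binary mask
as_binary_section <- function(section) {
  cross_section(section$lumen_mask, section$pixel_spacing, section$z)
}
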