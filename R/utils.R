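# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal integral of y over x
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) stop("trapz needs at least two points")
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Evaluate `expr` under a temporary RNG state.
#'
#' Restores (or removes) .Random.seed afterwards so seeded generators do not
#' disturb the caller's random stream. `seed = NULL` runs unseeded.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a bounded child seed from a parent seed (kept < 2^31)
#' @noRd
child_seed <- function(seed, i) {
  (as.numeric(seed) * 1009 + 97 * i) %% 2147483647
}

#' FNV-1a style hash of a character scalar, returned as 8 hex digits.
#'
#' Used to stamp outputs with a configuration fingerprint; plain base R so
#' reports carry no extra dependency.
#' @noRd
fnv1a_hash <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  lo <- h %% 65536; hi <- (h - lo) / 65536
  sprintf("%04x%04x", hi, lo)
}

#' Shift a matrix by (di, dj), filling vacated cells with `fill`
#' @noRd
shift_mat <- function(m, di, dj, fill = 0L) {
  out <- matrix(fill, nrow(m), ncol(m))
  ri <- seq_len(nrow(m)); ci <- seq_len(ncol(m))
  rs <- ri - di; cs <- ci - dj
  ok_r <- rs >= 1L & rs <= nrow(m); ok_c <- cs >= 1L & cs <= ncol(m)
  out[ri[ok_r], ci[ok_c]] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' 4-connected component labels of a logical matrix.
#'
#' Vectorised label propagation (min over neighbours until stable); adequate
#' for the raster sizes met here.
#' @noRd
label_components <- function(mask) {
  lab <- matrix(0, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  big <- sum(mask) + 1
  repeat {
    cur <- ifelse(mask, lab, big)
    nb <- pmin(
      shift_mat(cur, 1L, 0L, big), shift_mat(cur, -1L, 0L, big),
      shift_mat(cur, 0L, 1L, big), shift_mat(cur, 0L, -1L, big)
    )
    new <- ifelse(mask, pmin(cur, nb), 0)
    if (identical(new, ifelse(mask, cur, 0))) break
    lab <- new
  }
  lab[!mask] <- 0
  # compact labels
  u <- sort(unique(lab[lab > 0]))
  lab[] <- match(lab, u, nomatch = 0L) # 0 stays 0 since 0 not in u
  lab[!mask] <- 0L
  storage.mode(lab) <- "integer"
  lab
}

#' Binary erosion with the 3x3 (8-connected) structuring element, `width` times
#' @noRd
erode_binary <- function(m, width) {
  for (k in seq_len(width)) {
    e <- m
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      e <- e & shift_mat(m, di, dj, FALSE)
    }
    m <- e
  }
  m
}

#' Separable 2D FIR filtering with replicate edge padding
#' @param m numeric matrix
#' @param k odd-length 1D kernel
#' @noRd
filter2_sep <- function(m, k) {
  p <- (length(k) - 1L) %/% 2L
  if (nrow(m) < length(k) || ncol(m) < length(k))
    stop("image (", nrow(m), "x", ncol(m), ") smaller than filter kernel (",
         length(k), " taps)")
  mp <- m[c(rep(1L, p), seq_len(nrow(m)), rep(nrow(m), p)),
          c(rep(1L, p), seq_len(ncol(m)), rep(ncol(m), p)), drop = FALSE]
  a <- apply(mp, 2L, function(col) stats::filter(col, k, sides = 2L))
  a <- t(apply(t(a), 2L, function(col) stats::filter(col, k, sides = 2L)))
  a[(p + 1L):(p + nrow(m)), (p + 1L):(p + ncol(m)), drop = FALSE]
}

#' Gaussian smoothing of a matrix (separable, zero padding)
#' @noRd
smooth_gauss <- function(m, sd_px) {
  r <- max(2L, ceiling(4 * sd_px))
  k <- stats::dnorm(seq(-r, r), sd = sd_px)
  k <- k / sum(k)
  p <- r
  mp <- matrix(0, nrow(m) + 2L * p, ncol(m) + 2L * p)
  mp[(p + 1L):(p + nrow(m)), (p + 1L):(p + ncol(m))] <- m
  a <- apply(mp, 2L, function(col) stats::filter(col, k, sides = 2L))
  a <- t(apply(t(a), 2L, function(col) stats::filter(col, k, sides = 2L)))
  a[(p + 1L):(p + nrow(m)), (p + 1L):(p + ncol(m)), drop = FALSE]
}

#' Total polyline length of closed contour segments from contourLines
#' @noRd
contour_length <- function(cl) {
  sum(vapply(cl, function(cc) {
    x <- c(cc$x, cc$x[1L]); y <- c(cc$y, cc$y[1L])
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }, numeric(1)))
}
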