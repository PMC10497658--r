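# Decoding cardiac-induced tissue displacement from cine DENSE image series.
#
# DENSE encodes tissue displacement linearly into image phase at a known
# encoding frequency k_e (cycles/mm): u = phase / (2 pi k_e). Phase is only
# observed wrapped to (-pi, pi], so displacements beyond half an encoding
# wavelength need spatial unwrapping before decoding. Arrays are stored
# [row, col, frame].

#' A cine DENSE series (magnitude + two phase channels)
#'
#' @param magnitude array `rows x cols x frames`, arbitrary intensity units.
#' @param phase_ap,phase_cc phase arrays (radians) for the anterior-posterior
#'   and cranial-caudal encoding directions; wrapped to (-pi, pi] unless
#'   `unwrapped = TRUE`.
#' @param pixel_size in-plane pixel size in mm (default 0.9).
#' @param frame_interval temporal resolution per frame in ms (default 34).
#' @param ke displacement encoding frequency in cycles/mm (default 0.6).
#' @param unwrapped logical; phases already unwrapped (may exceed pi).
#' @return An object of class `dense_series`.
#' @export
dense_series <- function(magnitude, phase_ap, phase_cc, pixel_size = 0.9,
                         frame_interval = 34, ke = 0.6, unwrapped = FALSE) {
  dm <- dim(magnitude)
  if (length(dm) != 3L) stop("magnitude must be a rows x cols x frames array")
  if (!identical(dim(phase_ap), dm) || !identical(dim(phase_cc), dm))
    stop("magnitude and phase arrays must share dimensions")
  if (!is.numeric(ke) || ke <= 0) stop("encoding frequency ke must be > 0")
  if (pixel_size <= 0 || frame_interval <= 0)
    stop("pixel_size and frame_interval must be positive")
  if (!unwrapped) {
    rng <- range(phase_ap, phase_cc)
    if (rng[1L] <= -pi - 1e-9 || rng[2L] > pi + 1e-9)
      stop("wrapped phases must lie in (-pi, pi]")
  }
  structure(list(magnitude = magnitude, phase_ap = phase_ap,
                 phase_cc = phase_cc, pixel_size = pixel_size,
                 frame_interval = frame_interval, ke = ke,
                 unwrapped = unwrapped),
            class = "dense_series")
}

#' @export
print.dense_series <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf(
    "DENSE series: %dx%d px (%.2f mm), %d frames (%g ms), ke = %g c/mm%s\n",
    d[1L], d[2L], x$pixel_size, d[3L], x$frame_interval, x$ke,
    if (x$unwrapped) ", unwrapped" else ""))
  invisible(x)
}

#' Labelled brain-region mask for a DENSE slice
#'
#' @param labels integer matrix (0 = background) or character matrix
#'   ("background" plus region names).
#' @param pixel_size pixel size in mm.
#' @param region_names named integer vector mapping region name to label;
#'   inferred for character input, defaults to `c(cerebellum = 1, brainstem
#'   = 2)` for integer input covering those labels.
#' @param eroded logical; whether a boundary band has already been excluded.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(labels, pixel_size, region_names = NULL,
                        eroded = FALSE) {
  if (is.character(labels)) {
    nms <- setdiff(sort(unique(as.vector(labels))), "background")
    region_names <- stats::setNames(seq_along(nms), nms)
    lab <- matrix(0L, nrow(labels), ncol(labels))
    for (nm in nms) lab[labels == nm] <- region_names[[nm]]
    labels <- lab
  }
  if (!is.matrix(labels)) stop("labels must be a matrix")
  storage.mode(labels) <- "integer"
  if (is.null(region_names)) {
    u <- setdiff(sort(unique(as.vector(labels))), 0L)
    region_names <- stats::setNames(u, c("cerebellum", "brainstem",
                                         paste0("region", seq_along(u)))[seq_along(u)])
  }
  structure(list(labels = labels, pixel_size = pixel_size,
                 region_names = region_names, eroded = eroded),
            class = "region_mask")
}

#' Exclude a boundary band from each region
#'
#' Morphological erosion (8-connected) of every labelled region by `width`
#' voxels, excluding a boundary band where partial-volume contamination from
#' neighbouring structures is likely. Default width 2 ("two-to-three" voxels).
#'
#' @param mask a [region_mask()].
#' @param width band width in voxels (>= 0; 0 is the identity).
#' @return The eroded `region_mask` with `eroded = TRUE` (unless width 0).
#' @export
erode_region <- function(mask, width = 2L) {
  stopifnot(inherits(mask, "region_mask"))
  if (width < 0) stop("width must be >= 0")
  if (width == 0L) return(mask)
  out <- matrix(0L, nrow(mask$labels), ncol(mask$labels))
  for (nm in names(mask$region_names)) {
    lab <- mask$region_names[[nm]]
    e <- erode_binary(mask$labels == lab, width)
    if (!any(e))
      stop("region '", nm, "' vanished after erosion by ", width, " voxels")
    out[e] <- lab
  }
  region_mask(out, mask$pixel_size, mask$region_names, eroded = TRUE)
}

# wrap values to (-pi, pi]
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Quality-guided 2D unwrapping of one wrapped phase image within one region.
# Quality = negative sum of squared wrapped neighbour differences (phase
# derivative variance style). Grows from the best-quality seed; each new
# pixel is offset by the multiple of 2 pi that matches its highest-quality
# unwrapped neighbour.
unwrap_region <- function(phase, region) {
  idx <- which(region)
  nr <- nrow(phase)
  # fast path: no neighbour jump beyond pi anywhere in the region
  q <- numeric(length(idx))
  neigh <- vector("list", 4L)
  offs <- c(-1L, 1L, -nr, nr)
  needs <- FALSE
  inreg <- matrix(FALSE, nr, ncol(phase)); inreg[idx] <- TRUE
  for (k in 1:4) {
    nb <- idx + offs[k]
    ok <- nb >= 1L & nb <= length(phase)
    if (k <= 2L) ok <- ok & (((nb - 1L) %/% nr) == ((idx - 1L) %/% nr))
    ok[ok] <- inreg[nb[ok]]
    d <- rep(0, length(idx))
    d[ok] <- wrap_phase(phase[nb[ok]] - phase[idx[ok]])
    if (any(abs(phase[nb[ok]] - phase[idx[ok]]) > pi)) needs <- TRUE
    q <- q - d^2
    neigh[[k]] <- ifelse(ok, nb, NA_integer_)
  }
  if (!needs) return(phase)
  id <- matrix(0L, nr, ncol(phase)); id[idx] <- seq_along(idx)
  unw <- phase
  done <- logical(length(idx))
  infr <- logical(length(idx))
  seed <- which.max(q)
  done[seed] <- TRUE
  frontier <- integer(0)
  push_nbrs <- function(i, frontier) {
    for (k in 1:4) {
      nb <- neigh[[k]][i]
      if (!is.na(nb)) {
        j <- id[nb]
        if (!done[j] && !infr[j]) { infr[j] <<- TRUE; frontier <- c(frontier, j) }
      }
    }
    frontier
  }
  frontier <- push_nbrs(seed, frontier)
  while (length(frontier)) {
    b <- which.max(q[frontier])
    j <- frontier[b]
    frontier <- frontier[-b]
    infr[j] <- FALSE
    # best-quality unwrapped neighbour as reference
    ref <- NA_integer_; refq <- -Inf
    for (k in 1:4) {
      nb <- neigh[[k]][j]
      if (!is.na(nb)) {
        jj <- id[nb]
        if (done[jj] && q[jj] > refq) { refq <- q[jj]; ref <- jj }
      }
    }
    pj <- idx[j]
    unw[pj] <- phase[pj] + 2 * pi * round((unw[idx[ref]] - phase[pj]) / (2 * pi))
    done[j] <- TRUE
    frontier <- push_nbrs(j, frontier)
  }
  # spatial unwrapping leaves a global 2*pi*k ambiguity (the seed keeps its
  # wrapped value even when it sits inside a wrapped island); anchor the
  # region so its median phase lies within (-pi, pi]
  off <- 2 * pi * round(stats::median(unw[idx]) / (2 * pi))
  if (off != 0) unw[idx] <- unw[idx] - off
  unw
}

#' Spatial phase unwrapping within brain regions
#'
#' Quality-guided 2D unwrapping of both phase channels, applied per frame and
#' per region ("if needed": frames whose regional phase field has no
#' neighbour jump beyond pi are returned unchanged). Pixels outside regions
#' are untouched; output phases may exceed pi.
#'
#' @param series a [dense_series()] with wrapped phases.
#' @param mask a [region_mask()].
#' @return The unwrapped `dense_series`.
#' @export
unwrap_phase <- function(series, mask) {
  stopifnot(inherits(series, "dense_series"), inherits(mask, "region_mask"))
  nf <- dim(series$magnitude)[3L]
  ap <- series$phase_ap; cc <- series$phase_cc
  for (nm in names(mask$region_names)) {
    reg <- mask$labels == mask$region_names[[nm]]
    if (sum(reg) < 4L) {
      warning("region '", nm, "' smaller than 4 pixels; unwrapping skipped")
      next
    }
    for (k in seq_len(nf)) {
      ap[, , k] <- unwrap_region(ap[, , k], reg)
      cc[, , k] <- unwrap_region(cc[, , k], reg)
    }
  }
  dense_series(series$magnitude, ap, cc, series$pixel_size,
               series$frame_interval, series$ke, unwrapped = TRUE)
}

#' Decode phase into Eulerian displacement maps
#'
#' `u = phase / (2 pi k_e)` per encoding direction, converted to micrometres.
#'
#' @param series a [dense_series()] (unwrapped if wraps are possible).
#' @param mask optional [region_mask()]; when given, the validity mask is the
#'   union of labelled regions and displacement is zeroed outside it.
#' @return An object of class `displacement_maps`: arrays `ap` and `cc` (um),
#'   a logical `validity` matrix, `pixel_size`, `frame_interval`.
#' @export
phase_to_displacement <- function(series, mask = NULL) {
  stopifnot(inherits(series, "dense_series"))
  if (series$ke <= 0) stop("encoding frequency ke must be > 0")
  scale <- 1000 / (2 * pi * series$ke)  # rad -> um
  ap <- series$phase_ap * scale
  cc <- series$phase_cc * scale
  validity <- matrix(TRUE, dim(ap)[1L], dim(ap)[2L])
  if (!is.null(mask)) {
    validity <- mask$labels > 0L
    for (k in seq_len(dim(ap)[3L])) {
      a <- ap[, , k]; a[!validity] <- 0; ap[, , k] <- a
      b <- cc[, , k]; b[!validity] <- 0; cc[, , k] <- b
    }
  }
  structure(list(ap = ap, cc = cc, validity = validity,
                 pixel_size = series$pixel_size,
                 frame_interval = series$frame_interval),
            class = "displacement_maps")
}

#' The displacement-map noise filter kernel
#'
#' Hamming windowed-sinc FIR low-pass of the given order and normalized
#' cutoff (fraction of Nyquist), normalized to unit DC gain so that uniform
#' displacement fields pass unchanged.
#'
#' @param cutoff normalized cutoff frequency in (0, 1); default 0.15.
#' @param order filter order (even); the kernel has `order + 1` taps.
#' @return Numeric kernel of length `order + 1`.
#' @export
displacement_filter_kernel <- function(cutoff = 0.15, order = 16L) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  if (order %% 2L != 0L || order <= 0L) stop("order must be a positive even integer")
  k <- signal::fir1(order, cutoff)
  k / sum(k)
}

#' Spatial noise filtering of displacement maps
#'
#' Separable 2D low-pass: the 1D windowed-sinc kernel is applied along rows
#' then columns of each frame's map, with replicate edge padding. Defaults
#' follow the standard DENSE post-processing chain (cutoff 0.15, order 16).
#'
#' @param maps a `displacement_maps` object.
#' @param cutoff normalized cutoff frequency in (0, 1).
#' @param order filter order (even number of taps minus one).
#' @return Filtered `displacement_maps`.
#' @export
filter_displacement <- function(maps, cutoff = 0.15, order = 16L) {
  stopifnot(inherits(maps, "displacement_maps"))
  k <- displacement_filter_kernel(cutoff, order)
  for (fr in seq_len(dim(maps$ap)[3L])) {
    maps$ap[, , fr] <- filter2_sep(maps$ap[, , fr], k)
    maps$cc[, , fr] <- filter2_sep(maps$cc[, , fr], k)
  }
  maps
}

#' Displacement vector magnitude
#'
#' Euclidean norm of the (AP, CC) displacement components, per pixel and
#' frame.
#'
#' @param maps a `displacement_maps` object.
#' @return Array of magnitudes (um).
#' @export
displacement_magnitude <- function(maps) {
  sqrt(maps$ap^2 + maps$cc^2)
}

#' Peak regional displacement via a circular ROI
#'
#' Finds, within a (preferably eroded) region, the pixel whose displacement
#' magnitude peaks over the cardiac cycle, centres a circular ROI of
#' `roi_area` mm^2 there (shifting it minimally if it does not fit inside the
#' region), and reports the temporal maximum of the ROI statistic: the ROI's
#' spatial mean magnitude by default, or the spatial maximum with
#' `statistic = "max"`.
#'
#' @param maps a `displacement_maps` object.
#' @param mask a [region_mask()].
#' @param region region name (e.g. "cerebellum").
#' @param roi_area ROI area in mm^2 (default 30, radius ~ 3.09 mm).
#' @param statistic "mean" (default) or "max".
#' @return An object of class `displacement_summary`: `region`, `roi_center`
#'   (row, col), `roi_area_mm2`, `displacement_um`, `frame_of_peak`,
#'   `n_roi_px`, `statistic`.
#' @export
summarize_region <- function(maps, mask, region, roi_area = 30,
                             statistic = c("mean", "max")) {
  stopifnot(inherits(maps, "displacement_maps"), inherits(mask, "region_mask"))
  statistic <- match.arg(statistic)
  if (!region %in% names(mask$region_names))
    stop("region '", region, "' not present in mask")
  if (!mask$eroded)
    warning("region mask is not eroded; boundary voxels will be included")
  reg <- mask$labels == mask$region_names[[region]]
  if (!any(reg)) stop("region '", region, "' is empty")
  mag <- displacement_magnitude(maps)
  nf <- dim(mag)[3L]
  peak <- mag[, , 1L]
  for (k in seq_len(nf)[-1L]) peak <- pmax(peak, mag[, , k])
  peak_in <- peak; peak_in[!reg] <- -Inf
  am <- arrayInd(which.max(peak_in), dim(peak))
  r_px <- sqrt(roi_area / pi) / maps$pixel_size
  nr <- nrow(peak); nc <- ncol(peak)
  ro <- -floor(r_px):floor(r_px)
  offs <- expand.grid(di = ro, dj = ro)
  offs <- offs[offs$di^2 + offs$dj^2 <= r_px^2, ]
  fits <- function(ci, cj) {
    ri <- ci + offs$di; cj2 <- cj + offs$dj
    all(ri >= 1L & ri <= nr & cj2 >= 1L & cj2 <= nc) &&
      all(reg[cbind(ri, cj2)])
  }
  centre <- c(am[1L], am[2L])
  if (!fits(centre[1L], centre[2L])) {
    cand <- which(reg, arr.ind = TRUE)
    d2 <- (cand[, 1L] - am[1L])^2 + (cand[, 2L] - am[2L])^2
    cand <- cand[order(d2), , drop = FALSE]
    found <- FALSE
    for (i in seq_len(nrow(cand))) {
      if (fits(cand[i, 1L], cand[i, 2L])) {
        centre <- c(cand[i, 1L], cand[i, 2L]); found <- TRUE; break
      }
    }
    if (!found)
      stop("a ", roi_area, " mm^2 ROI does not fit inside region '", region,
           "'")
  }
  roi <- cbind(centre[1L] + offs$di, centre[2L] + offs$dj)
  per_frame <- vapply(seq_len(nf), function(k) {
    v <- mag[, , k][roi]
    if (statistic == "mean") mean(v) else max(v)
  }, numeric(1))
  structure(list(region = region, roi_center = centre,
                 roi_area_mm2 = nrow(roi) * maps$pixel_size^2,
                 displacement_um = max(per_frame),
                 frame_of_peak = which.max(per_frame),
                 n_roi_px = nrow(roi), statistic = statistic),
            class = "displacement_summary")
}

#' @export
print.displacement_summary <- function(x, ...) {
  cat(sprintf(
    "%s: displacement = %.1f um (ROI %.1f mm^2 at [%d, %d], frame %d, %s)\n",
    x$region, x$displacement_um, x$roi_area_mm2, x$roi_center[1L],
    x$roi_center[2L], x$frame_of_peak, x$statistic))
  invisible(x)
}

#' Full DENSE post-processing chain
#'
#' Erosion of the region mask, phase unwrapping (if needed), phase-to-
#' displacement decoding, spatial noise filtering, and ROI summarisation of
#' every region.
#'
#' @param series a [dense_series()] (wrapped phases).
#' @param mask a [region_mask()] (uneroded).
#' @param erode_width boundary exclusion width in voxels.
#' @param cutoff,order FIR filter parameters.
#' @param roi_area ROI area in mm^2.
#' @param statistic ROI statistic, "mean" or "max".
#' @return list with `summaries` (named list of [summarize_region()] results
#'   per region), `maps` (filtered displacement maps) and `mask_eroded`.
#' @export
dense_pipeline <- function(series, mask, erode_width = 2L, cutoff = 0.15,
                           order = 16L, roi_area = 30,
                           statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  me <- erode_region(mask, erode_width)
  unw <- unwrap_phase(series, me)
  maps <- phase_to_displacement(unw)
  maps <- filter_displacement(maps, cutoff, order)
  sums <- lapply(names(me$region_names), function(nm)
    summarize_region(maps, me, nm, roi_area, statistic))
  names(sums) <- names(me$region_names)
  list(summaries = sums, maps = maps, mask_eroded = me)
}

# --- I/O --------------------------------------------------------------------

#' Read a DENSE series from NIfTI volumes plus a JSON sidecar
#'
#' Expects `magnitude.nii`/`.nii.gz`, `phase_ap.nii`, `phase_cc.nii` (4D, one
#' volume per channel with frames along the 4th dimension collapsed to 3rd
#' for single-slice data) and `dense.json` with `ke_cycles_per_mm` and
#' `frame_interval_ms` in `dir`.
#'
#' @param dir directory path.
#' @return A [dense_series()].
#' @export
read_dense_nifti <- function(dir) {
  side <- file.path(dir, "dense.json")
  if (!file.exists(side)) stop("missing sidecar file: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  chan <- function(stem) {
    fs <- list.files(dir, pattern = paste0("^", stem, "\\.nii(\\.gz)?$"),
                     full.names = TRUE)
    if (!length(fs)) stop("missing DENSE channel file '", stem, "' in ", dir)
    a <- as.array(RNifti::readNifti(fs[1L]))
    if (length(dim(a)) == 4L) a <- a[, , 1L, , drop = TRUE]
    a
  }
  mg <- chan("magnitude")
  px <- RNifti::pixdim(RNifti::readNifti(list.files(
    dir, pattern = "^magnitude\\.nii(\\.gz)?$", full.names = TRUE)[1L]))[1L]
  dense_series(mg, chan("phase_ap"), chan("phase_cc"), pixel_size = px,
               frame_interval = meta$frame_interval_ms,
               ke = meta$ke_cycles_per_mm)
}

#' Write displacement maps as a 4D NIfTI volume (um)
#'
#' Channels AP and CC are stacked along the 4th dimension blocks.
#'
#' @param maps a `displacement_maps` object.
#' @param path output `.nii.gz` path.
#' @export
write_displacement_nifti <- function(maps, path) {
  d <- dim(maps$ap)
  arr <- array(0, c(d[1L], d[2L], 2L, d[3L]))
  arr[, , 1L, ] <- maps$ap
  arr[, , 2L, ] <- maps$cc
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(maps$pixel_size, maps$pixel_size, 1,
                           maps$frame_interval)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write region displacement summaries to JSON and CSV
#'
#' @param summaries named list of [summarize_region()] results.
#' @param path output path without extension.
#' @param subject optional subject identifier column.
#' @export
write_displacement_summary <- function(summaries, path, subject = NA) {
  df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(subject = subject, region = s$region,
               displacement_um = s$displacement_um,
               roi_row = s$roi_center[1L], roi_col = s$roi_center[2L],
               roi_area_mm2 = s$roi_area_mm2)))
  jsonlite::write_json(df, paste0(path, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  invisible(df)
}
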