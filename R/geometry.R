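# Canal geometry: segmented cross-sections of the spinal subarachnoid space
# and their hydraulic metrics. All hydrodynamic quantities are computed in CGS
# units (cm, g, s, dyn); raster spacing and axial positions enter in mm and
# are converted at the boundary.

#' CSF fluid properties
#'
#' Cerebrospinal fluid is modelled as water at body temperature.
#'
#' @param density_rho fluid density in g/cm^3 (default 1.0).
#' @param viscosity_mu dynamic viscosity in poise (default 0.01).
#' @return An object of class `fluid_props`.
#' @export
fluid_props <- function(density_rho = 1.0, viscosity_mu = 0.01) {
  if (!is.numeric(density_rho) || density_rho <= 0)
    stop("density_rho must be positive")
  if (!is.numeric(viscosity_mu) || viscosity_mu <= 0)
    stop("viscosity_mu must be positive")
  structure(list(density_rho = density_rho, viscosity_mu = viscosity_mu),
            class = "fluid_props")
}

#' A single segmented canal cross-section
#'
#' Represents the CSF lumen in one axial slice as a binary raster. The lumen
#' of the spinal subarachnoid space is annular: both the inner (cord) and the
#' outer (dura) surfaces are walls.
#'
#' @param lumen_mask logical (or 0/1 numeric) matrix; `TRUE` marks lumen.
#' @param pixel_spacing in-plane pixel spacing in mm (isotropic).
#' @param z axial position in mm caudal to the foramen magnum.
#' @param sdf optional signed distance to the lumen wall (mm, positive
#'   inside), same dimensions as `lumen_mask`. When present it enables
#'   sub-pixel boundary treatment in the perimeter estimate and the
#'   oscillatory-flow solver.
#' @param coverage optional fractional pixel coverage in \[0, 1\].
#' @return An object of class `cross_section`.
#' @details Sections with fewer than 10 lumen pixels, non-positive spacing or
#'   lumen touching the raster border are rejected. Disconnected lumen
#'   fragments smaller than 10 pixels (segmentation debris) are dropped with
#'   a warning; several genuine components are retained with a warning.
#' @export
cross_section <- function(lumen_mask, pixel_spacing, z, sdf = NULL,
                          coverage = NULL) {
  if (is.numeric(lumen_mask)) lumen_mask <- lumen_mask >= 0.5
  if (!is.logical(lumen_mask) || !is.matrix(lumen_mask))
    stop("lumen_mask must be a logical matrix")
  if (anyNA(lumen_mask)) stop("lumen_mask contains NA")
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      pixel_spacing <= 0)
    stop("pixel_spacing must be a positive scalar (mm)")
  if (sum(lumen_mask) == 0L) stop("geometry error: empty lumen mask")
  if (any(lumen_mask[1L, ]) || any(lumen_mask[nrow(lumen_mask), ]) ||
      any(lumen_mask[, 1L]) || any(lumen_mask[, ncol(lumen_mask)]))
    stop("geometry error: lumen mask touches the raster border; ",
         "the wall must close inside the frame")
  lab <- label_components(lumen_mask)
  ncomp <- max(lab)
  if (ncomp > 1L) {
    sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
    small <- which(sizes < 10L)
    if (length(small)) {
      lumen_mask[lab %in% small] <- FALSE
      warning("dropped ", length(small),
              " lumen fragment(s) smaller than 10 pixels")
    }
    if (sum(sizes >= 10L) > 1L)
      warning("lumen has ", sum(sizes >= 10L),
              " disjoint components; all retained")
  }
  if (sum(lumen_mask) < 10L)
    stop("geometry error: fewer than 10 lumen pixels")
  if (!is.null(sdf) && !all(dim(sdf) == dim(lumen_mask)))
    stop("sdf dimensions must match lumen_mask")
  if (!is.null(coverage) && !all(dim(coverage) == dim(lumen_mask)))
    stop("coverage dimensions must match lumen_mask")
  structure(list(lumen_mask = lumen_mask, pixel_spacing = pixel_spacing,
                 z = z, sdf = sdf, coverage = coverage),
            class = "cross_section")
}

#' Ordered stack of canal cross-sections
#'
#' @param sections list of [cross_section()] objects ordered caudally, the
#'   first at the foramen magnum (z = 0), the last at 25 mm or beyond so the
#'   impedance segment is covered.
#' @return An object of class `canal_geometry`.
#' @export
canal_geometry <- function(sections) {
  if (!length(sections) || !all(vapply(sections, inherits, TRUE, "cross_section")))
    stop("sections must be a non-empty list of cross_section objects")
  z <- vapply(sections, `[[`, numeric(1), "z")
  if (any(diff(z) <= 0)) stop("section z positions must be strictly increasing")
  if (abs(z[1L]) > 1e-6) stop("first section must sit at the foramen magnum (z = 0)")
  if (z[length(z)] < 25) stop("last section must reach z >= 25 mm")
  structure(list(sections = sections, z = z), class = "canal_geometry")
}

#' Hydraulic metrics of a cross-section
#'
#' Area, wetted perimeter and hydraulic diameter `D_H = 4 A / P` of the lumen,
#' in cm. Both inner and outer boundary contours count toward the wetted
#' perimeter. The boundary is traced sub-pixel: the zero level of the signed
#' distance field when the section carries one, otherwise the 0.5 isocontour
#' of the lightly smoothed binary mask (a raw binary isocontour overestimates
#' perimeter by several percent).
#'
#' @param section a [cross_section()].
#' @return An object of class `section_metrics` with fields `area_cm2`,
#'   `perimeter_cm`, `dh_cm` and `n_pixels`.
#' @export
section_metrics <- function(section) {
  stopifnot(inherits(section, "cross_section"))
  h_cm <- section$pixel_spacing / 10
  area <- if (!is.null(section$coverage)) sum(section$coverage) * h_cm^2
          else sum(section$lumen_mask) * h_cm^2
  nr <- nrow(section$lumen_mask); nc <- ncol(section$lumen_mask)
  xs <- seq_len(nr) * h_cm; ys <- seq_len(nc) * h_cm
  if (!is.null(section$sdf)) {
    cl <- grDevices::contourLines(xs, ys, section$sdf / 10, levels = 0)
  } else {
    z <- smooth_gauss(section$lumen_mask * 1.0, 1.0)
    cl <- grDevices::contourLines(xs, ys, z, levels = 0.5)
  }
  if (!length(cl)) stop("geometry error: no boundary contour found")
  per <- contour_length(cl)
  structure(list(area_cm2 = area, perimeter_cm = per,
                 dh_cm = 4 * area / per, n_pixels = sum(section$lumen_mask)),
            class = "section_metrics")
}

#' Peak Reynolds number of the CSF flow
#'
#' `Re = 4 rho Q / (pi mu D_H)` for a peak volumetric flow `Q` through a
#' conduit with hydraulic diameter `D_H`.
#'
#' @param peak_flow_Q peak volumetric flow in cm^3/s (>= 0).
#' @param props [fluid_props()].
#' @param metrics [section_metrics()] of the evaluation slice (conventionally
#'   the inlet, z = 0).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(peak_flow_Q, props = fluid_props(), metrics) {
  stopifnot(inherits(props, "fluid_props"), inherits(metrics, "section_metrics"))
  if (!is.numeric(peak_flow_Q) || peak_flow_Q < 0) stop("peak flow must be >= 0")
  if (metrics$dh_cm <= 0) stop("hydraulic diameter must be positive")
  4 * props$density_rho * peak_flow_Q /
    (pi * props$viscosity_mu * metrics$dh_cm)
}

#' Per-slice hydraulic metrics of a canal geometry
#'
#' @param x a [canal_geometry()].
#' @param ... unused.
#' @return data.frame with columns `z_mm`, `area_cm2`, `perimeter_cm`, `dh_cm`.
#' @export
as.data.frame.canal_geometry <- function(x, ...) {
  rows <- lapply(x$sections, function(s) {
    m <- section_metrics(s)
    data.frame(z_mm = s$z, area_cm2 = m$area_cm2,
               perimeter_cm = m$perimeter_cm, dh_cm = m$dh_cm)
  })
  do.call(rbind, rows)
}

#' Write the per-slice metrics table to CSV
#'
#' @param geometry a [canal_geometry()].
#' @param path output CSV path.
#' @return The metrics data.frame, invisibly.
#' @export
write_section_metrics <- function(geometry, path) {
  df <- as.data.frame(geometry)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @export
print.canal_geometry <- function(x, ...) {
  cat("Canal geometry:", length(x$sections), "sections, z =",
      sprintf("%.1f", min(x$z)), "to", sprintf("%.1f", max(x$z)), "mm\n")
  invisible(x)
}

#' @export
print.section_metrics <- function(x, ...) {
  cat(sprintf("A = %.4f cm^2, P = %.4f cm, D_H = %.4f cm (%d px)\n",
              x$area_cm2, x$perimeter_cm, x$dh_cm, x$n_pixels))
  invisible(x)
}

#' Read a canal geometry from a NIfTI segmentation volume
#'
#' One axial slice per section; in-plane spacing and slice thickness are taken
#' from the header. Voxels > 0.5 are lumen.
#'
#' @param path NIfTI file.
#' @param z0 axial position (mm) of the first slice relative to the foramen
#'   magnum; default 0.
#' @return A [canal_geometry()].
#' @export
read_canal_nifti <- function(path, z0 = 0) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (abs(pd[1L] - pd[2L]) > 1e-6)
    stop("anisotropic in-plane spacing is not supported")
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D volume")
  secs <- lapply(seq_len(dim(arr)[3L]), function(k)
    cross_section(arr[, , k] > 0.5, pixel_spacing = pd[1L],
                  z = z0 + (k - 1L) * pd[3L]))
  canal_geometry(secs)
}

#' Read a canal geometry from a directory of PNG slices
#'
#' The directory must contain one PNG per axial slice (sorted by filename,
#' cranial to caudal) and a `geometry.json` sidecar with fields
#' `pixel_spacing_mm`, `slice_thickness_mm` and `z0_mm`.
#'
#' @param dir directory path.
#' @return A [canal_geometry()].
#' @export
read_canal_png <- function(dir) {
  side <- file.path(dir, "geometry.json")
  if (!file.exists(side)) stop("missing sidecar file: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG slices in ", dir)
  secs <- lapply(seq_along(files), function(k) {
    img <- png::readPNG(files[k])
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    cross_section(img > 0.5, pixel_spacing = meta$pixel_spacing_mm,
                  z = meta$z0_mm + (k - 1L) * meta$slice_thickness_mm)
  })
  canal_geometry(secs)
}
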