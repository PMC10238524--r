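#' Parallel-beam scan geometry
#'
#' Defines the acquisition geometry shared by the forward projector, the
#' filtered back-projector, the simulator and every correction method:
#' `n_angles` view angles evenly spaced over the half circle `[0, pi)`, a
#' 1-D detector of `n_bins` bins, and the reconstruction grid.  The detector
#' must cover the image diagonal so no part of the support is truncated.
#'
#' @param image_shape integer vector `c(rows, cols)` of the reconstruction grid.
#' @param n_angles number of projection angles over `[0, pi)`.
#' @param pixel_spacing pixel size in mm.
#' @param n_bins detector bin count; default is the smallest odd integer
#'   covering the image diagonal (an odd count puts a bin exactly on the
#'   rotation axis).
#' @param bin_spacing detector bin size in mm; defaults to `pixel_spacing`.
#' @return an object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry(c(128, 128), n_angles = 120)
#' g$n_bins
#' @export
scan_geometry <- function(image_shape, n_angles = 180, pixel_spacing = 1,
                          n_bins = NULL, bin_spacing = pixel_spacing) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2 || any(image_shape < 1)) {
    abort_mvmar("image_shape must be two positive integers", "mvmar_geometry_error")
  }
  if (n_angles < 1) abort_mvmar("n_angles must be >= 1", "mvmar_geometry_error")
  diag_px <- sqrt(sum((image_shape * pixel_spacing / bin_spacing)^2))
  min_bins <- ceiling(diag_px)
  if (is.null(n_bins)) {
    n_bins <- min_bins + (min_bins %% 2 == 0) # make odd
  } else if (n_bins < min_bins) {
    abort_mvmar(sprintf(
      "n_bins = %d truncates the image support (need >= %d)", n_bins, min_bins
    ), "mvmar_geometry_error")
  }
  angles <- seq(0, pi, length.out = n_angles + 1)[seq_len(n_angles)]
  structure(list(
    n_angles = as.integer(n_angles),
    angles = angles,
    n_bins = as.integer(n_bins),
    bin_spacing = bin_spacing,
    image_shape = image_shape,
    pixel_spacing = pixel_spacing
  ), class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "<scan_geometry> %d angles over [0, pi), %d bins x %.3g mm, grid %dx%d @ %.3g mm\n",
    x$n_angles, x$n_bins, x$bin_spacing, x$image_shape[1], x$image_shape[2],
    x$pixel_spacing
  ))
  invisible(x)
}

#' CT slice image
#'
#' A 2-D grid of CT values (Hounsfield units for scanner-calibrated images)
#' with its pixel spacing and a modality tag.
#'
#' @param values numeric matrix of pixel values.
#' @param pixel_spacing pixel size in mm.
#' @param modality one of `"kV"`, `"MV"`, `"template"`, `"corrected"`,
#'   `"artifact"`, `"unknown"`.
#' @return an object of class `slice_image`.
#' @export
slice_image <- function(values, pixel_spacing = 1, modality = "unknown") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot_finite(values, "slice image")
  modality <- match.arg(modality,
    c("unknown", "kV", "MV", "template", "corrected", "artifact"))
  structure(list(values = values, pixel_spacing = pixel_spacing,
                 modality = modality),
            class = "slice_image")
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image %s> %dx%d @ %.3g mm, range [%.1f, %.1f]\n",
              x$modality, nrow(x$values), ncol(x$values), x$pixel_spacing,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.slice_image <- function(x) dim(x$values)

#' Sinogram container
#'
#' Line integrals arranged as an `n_angles x n_bins` matrix tied to the
#' geometry that produced them.
#'
#' @param values numeric `n_angles x n_bins` matrix.
#' @param geometry the [scan_geometry()] the sinogram belongs to.
#' @return an object of class `sinogram`.
#' @export
sinogram <- function(values, geometry) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!identical(dim(values), c(geometry$n_angles, geometry$n_bins))) {
    abort_mvmar(sprintf(
      "sinogram shape %dx%d does not match geometry (%d angles x %d bins)",
      nrow(values), ncol(values), geometry$n_angles, geometry$n_bins
    ), "mvmar_geometry_error")
  }
  stopifnot_finite(values, "sinogram")
  structure(list(values = values, geometry = geometry), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d angles x %d bins, range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.sinogram <- function(x) dim(x$values)

# Pixel-center world coordinates (mm): x to the right along columns, y up
# along decreasing rows, origin at the grid center (= rotation axis).
grid_coords <- function(geometry) {
  nr <- geometry$image_shape[1]; nc <- geometry$image_shape[2]
  ps <- geometry$pixel_spacing
  xs <- (seq_len(nc) - (nc + 1) / 2) * ps
  ys <- ((nr + 1) / 2 - seq_len(nr)) * ps
  list(
    x = matrix(xs, nr, nc, byrow = TRUE),
    y = matrix(ys, nr, nc)
  )
}

check_image_geometry <- function(image, geometry) {
  if (!identical(dim(image$values), geometry$image_shape)) {
    abort_mvmar(sprintf(
      "image shape %dx%d does not match geometry grid %dx%d",
      nrow(image$values), ncol(image$values),
      geometry$image_shape[1], geometry$image_shape[2]
    ), "mvmar_geometry_error")
  }
  invisible(TRUE)
}
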