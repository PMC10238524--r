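#' Build the artifact-free template image
#'
#' The template copies the source image inside the high-density region M1
#' and replaces the medium-density region M2 and low-density region M3 by
#' the mean source value over each region.  Means are taken over ALL
#' region pixels of the slice, artifact-corrupted ones included; the
#' iteration loop is what progressively de-biases them as the corrected
#' image improves.
#'
#' @param source a [slice_image()] (the kV image, or the current corrected
#'   image on later iterations).
#' @param masks a [tissue_masks()] partition.
#' @param iteration iteration index recorded on the template.
#' @return a [slice_image()] with modality `"template"` and attributes
#'   `fill_means` (named means for M2/M3), `pixel_counts`, `iteration`.
#' @export
build_template <- function(source, masks, iteration = 0L) {
  v <- source$values
  if (!identical(dim(v), dim(masks$m1))) {
    abort_mvmar("source and masks shapes differ", "mvmar_geometry_error")
  }
  n2 <- sum(masks$m2); n3 <- sum(masks$m3)
  mean2 <- NA_real_; mean3 <- NA_real_
  out <- v
  if (n2 > 0) {
    mean2 <- sum(v[masks$m2]) / n2
    out[masks$m2] <- mean2
  } else {
    warning("M2 (soft tissue) is empty; fill skipped")
  }
  if (n3 > 0) {
    mean3 <- sum(v[masks$m3]) / n3
    out[masks$m3] <- mean3
  } else {
    warning("M3 (low density) is empty; fill skipped")
  }
  tmpl <- slice_image(out, source$pixel_spacing, "template")
  attr(tmpl, "fill_means") <- c(mean_M2 = mean2, mean_M3 = mean3)
  attr(tmpl, "pixel_counts") <- c(N_M2 = n2, N_M3 = n3)
  attr(tmpl, "iteration") <- as.integer(iteration)
  tmpl
}
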