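# In-trace linear interpolation of a sinogram: per angle and per run,
# values across [k1, k2] are replaced by the line between the values at
# k1-1 and k2+1; a run touching the detector edge uses the nearest
# available outside value on that side.
interpolate_trace <- function(p, trace) {
  nb <- ncol(p)
  for (a in seq_len(nrow(p))) {
    runs <- trace$runs[[a]]
    if (is.null(runs) || nrow(runs) == 0) next
    row <- p[a, ]
    for (r in seq_len(nrow(runs))) {
      k1 <- runs[r, 1]; k2 <- runs[r, 2]
      kl <- k1 - 1L; kr <- k2 + 1L
      vl <- if (kl >= 1) row[kl] else if (kr <= nb) row[kr] else 0
      vr <- if (kr <= nb) row[kr] else vl
      if (kl < 1) vl <- vr
      ks <- k1:k2
      row[ks] <- vl + (vr - vl) * (ks - (k1 - 1)) / (k2 + 1 - (k1 - 1))
    }
    p[a, ] <- row
  }
  p
}

# Both baselines project HU + offset so interpolation / normalization act
# on nonnegative sinograms; the offset cancels in the difference-form
# reconstruction corrected = kv - FBP(original - inpainted).
.baseline_offset <- 1000

#' Linear-interpolation MAR (LIMAR) baseline
#'
#' Classical projection-domain inpainting: within the metal trace, each
#' run of sinogram bins is replaced by linear interpolation between the
#' flanking non-metal projection values; the image is reconstructed and
#' the metal pixels are restored from the kV image.  Implemented in
#' difference form, `kv - FBP(FP(kv + 1000) - inpainted)`, which is
#' algebraically identical (FBP is linear) but keeps the image outside
#' the metal trace untouched by the FBP round trip.
#'
#' @param kv a kV [slice_image()].
#' @param metal a [metal_mask()].
#' @param geometry a [scan_geometry()].
#' @param filter_name FBP filter.
#' @param trace optional precomputed [metal_trace()].
#' @return the corrected [slice_image()].
#' @export
limar <- function(kv, metal, geometry, filter_name = "ramp", trace = NULL) {
  check_image_geometry(kv, geometry)
  if (is.null(trace)) trace <- metal_trace(metal, geometry)
  if (!any(trace$mask)) return(slice_image(kv$values, kv$pixel_spacing, "corrected"))
  p <- .fp_matrix(kv$values + .baseline_offset, geometry)
  p_in <- interpolate_trace(p, trace)
  corr <- kv$values - .fbp_matrix(p - p_in, geometry, filter_name)
  corr[metal$mask] <- kv$values[metal$mask]
  slice_image(corr, kv$pixel_spacing, "corrected")
}

#' Normalized MAR (NMAR) baseline
#'
#' Prior-normalized projection inpainting: a piecewise prior is built from
#' the kV image itself (air below `air_hu` set to -1000 HU, soft tissue
#' set to 0 HU, bone above `bone_hu` kept, metal pixels set to the soft
#' value), the kV sinogram is divided by the prior sinogram, the metal
#' trace of the normalized sinogram is linearly interpolated, and the
#' result is denormalized and reconstructed.  Difference-form
#' reconstruction and metal restoration as in [limar()].
#'
#' @inheritParams limar
#' @param air_hu,bone_hu prior classification thresholds.
#' @param denom_floor relative floor on the prior sinogram used as
#'   normalization denominator.
#' @return the corrected [slice_image()].
#' @export
nmar <- function(kv, metal, geometry, air_hu = -700, bone_hu = 300,
                 denom_floor = 1e-3, filter_name = "ramp", trace = NULL) {
  check_image_geometry(kv, geometry)
  if (is.null(trace)) trace <- metal_trace(metal, geometry)
  if (!any(trace$mask)) return(slice_image(kv$values, kv$pixel_spacing, "corrected"))
  prior <- kv$values
  prior[prior < air_hu] <- -1000
  prior[prior >= air_hu & prior <= bone_hu] <- 0
  prior[metal$mask] <- 0
  p <- .fp_matrix(kv$values + .baseline_offset, geometry)
  q <- .fp_matrix(prior + .baseline_offset, geometry)
  q <- pmax(q, denom_floor * max(q))
  norm <- p / q
  norm_in <- interpolate_trace(norm, trace)
  p_in <- norm_in * q
  corr <- kv$values - .fbp_matrix(p - p_in, geometry, filter_name)
  corr[metal$mask] <- kv$values[metal$mask]
  slice_image(corr, kv$pixel_spacing, "corrected")
}
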