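#' MAR configuration
#'
#' Tunable parameters of the correction engine.
#'
#' @param iterations number of template/correction passes (>= 1).  Three or
#'   four passes are typical; the default is 3.
#' @param delta_n1,delta_n2 boundary extension distances (detector bins, >= 1)
#'   of the linear ramps smoothing the metal-trace difference to zero.
#' @param hff_sigma_mm Gaussian low-pass width (mm) of the high-frequency
#'   filtering applied to the reconstructed artifact image; a physical
#'   width keeps the filter's effect independent of grid resolution
#'   (1.5 mm is 1.5 px on the reference 1 mm grid).
#' @param metal_threshold_hu kV threshold for metal segmentation.
#' @param block block size (pixels) of the prior segmentation.
#' @param trace_epsilon metal-trace support cutoff, as a fraction of the
#'   maximum of the projected metal mask (kills projector interpolation dust).
#' @param min_metal_area smallest metal component kept (pixels).
#' @param filter_name FBP filter used throughout.
#' @return an object of class `mar_config`.
#' @export
mar_config <- function(iterations = 3, delta_n1 = 4, delta_n2 = 4,
                       hff_sigma_mm = 1.5, metal_threshold_hu = 2500,
                       block = 8, trace_epsilon = 1e-6, min_metal_area = 4,
                       filter_name = "ramp") {
  if (iterations < 1) abort_mvmar("iterations must be >= 1", "mvmar_validation_error")
  if (delta_n1 < 1 || delta_n2 < 1) abort_mvmar("boundary extensions must be >= 1",
                                                "mvmar_validation_error")
  structure(list(iterations = as.integer(iterations),
                 delta_n1 = as.integer(delta_n1), delta_n2 = as.integer(delta_n2),
                 hff_sigma_mm = hff_sigma_mm, metal_threshold_hu = metal_threshold_hu,
                 block = as.integer(block), trace_epsilon = trace_epsilon,
                 min_metal_area = min_metal_area, filter_name = filter_name),
            class = "mar_config")
}

#' Metal trace in the sinogram
#'
#' Forward-projects the metal mask and thresholds the result at
#' `trace_epsilon` times its maximum: the trace marks every sinogram cell
#' whose ray crosses metal.  Maximal contiguous runs of trace bins are
#' extracted per angle (their first/last bins are the interpolation
#' boundaries downstream).
#'
#' @param metal a [metal_mask()].
#' @param geometry a [scan_geometry()].
#' @param trace_epsilon relative support cutoff.
#' @return an object of class `metal_trace`: logical `mask`
#'   (angles x bins) and `runs`, a list (one per angle) of two-column
#'   matrices `cbind(k1, k2)`.
#' @export
metal_trace <- function(metal, geometry, trace_epsilon = 1e-6) {
  if (!identical(dim(metal$mask), geometry$image_shape)) {
    abort_mvmar("metal mask shape does not match geometry", "mvmar_geometry_error")
  }
  proj <- .fp_matrix(matrix(as.numeric(metal$mask), nrow(metal$mask)), geometry)
  mx <- max(proj)
  tr <- if (mx <= 0) proj > Inf else proj > trace_epsilon * mx
  runs <- lapply(seq_len(nrow(tr)), function(a) {
    r <- rle(tr[a, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(k1 = starts[r$values], k2 = ends[r$values])
  })
  structure(list(mask = tr, runs = runs, trace_epsilon = trace_epsilon),
            class = "metal_trace")
}

#' Metal-trace sinogram difference
#'
#' The difference between the kV sinogram and the template sinogram,
#' restricted to the metal trace and exactly zero outside it.  Because the
#' template is filled with kV regional means, this difference inside the
#' trace is dominated by the metal-induced signal deviation, i.e. the
#' artifact content.
#'
#' @param kv_sino,template_sino [sinogram()]s under the same geometry.
#' @param trace a [metal_trace()].
#' @return a [sinogram()].
#' @export
sinogram_difference <- function(kv_sino, template_sino, trace) {
  if (!identical(dim(kv_sino$values), dim(template_sino$values))) {
    abort_mvmar("sinogram shapes differ", "mvmar_geometry_error")
  }
  d <- matrix(0, nrow(kv_sino$values), ncol(kv_sino$values))
  d[trace$mask] <- kv_sino$values[trace$mask] - template_sino$values[trace$mask]
  sinogram(d, kv_sino$geometry)
}

#' Smooth the trace boundaries of the difference sinogram
#'
#' A hard cut of the difference at the trace boundary would itself
#' back-project into new streaks, so each trace run keeps its interior
#' values and is extended by linear ramps that fall to zero: over
#' `[k1 - delta_n1, k1)` the value rises linearly from 0 to the run's
#' boundary value, and over `(k2, k2 + delta_n2]` it falls linearly from
#' the boundary value back to 0.  Everything outside runs and ramps is
#' zero.  Where extension zones of adjacent runs overlap, the ramp values
#' are summed and clipped to the larger boundary magnitude; ramps running
#' off the detector edge are truncated.
#'
#' @param diff a [sinogram_difference()] result.
#' @param trace the [metal_trace()] used to build it.
#' @param delta_n1,delta_n2 extension distances in bins (>= 1).
#' @return a [sinogram()].
#' @export
smooth_boundaries <- function(diff, trace, delta_n1 = 4, delta_n2 = 4) {
  if (delta_n1 < 1 || delta_n2 < 1) {
    abort_mvmar("boundary extensions must be >= 1", "mvmar_validation_error")
  }
  nb <- ncol(diff$values)
  out <- matrix(0, nrow(diff$values), nb)
  for (a in seq_len(nrow(out))) {
    runs <- trace$runs[[a]]
    if (is.null(runs) || nrow(runs) == 0) next
    row <- diff$values[a, ]
    orow <- numeric(nb)
    in_run <- logical(nb)
    for (r in seq_len(nrow(runs))) {
      idx <- runs[r, 1]:runs[r, 2]
      orow[idx] <- row[idx]
      in_run[idx] <- TRUE
    }
    ramp_sum <- numeric(nb)
    ramp_cap <- numeric(nb)
    add_ramp <- function(ks, vals, bval) {
      ok <- ks >= 1 & ks <= nb
      ks <- ks[ok]; vals <- vals[ok]
      free <- !in_run[ks]
      ks <- ks[free]; vals <- vals[free]
      ramp_sum[ks] <<- ramp_sum[ks] + vals
      ramp_cap[ks] <<- pmax(ramp_cap[ks], abs(bval))
    }
    for (r in seq_len(nrow(runs))) {
      k1 <- runs[r, 1]; k2 <- runs[r, 2]
      b1 <- row[k1]; b2 <- row[k2]
      if (delta_n1 >= 1 && b1 != 0) {
        ks <- (k1 - delta_n1):(k1 - 1)
        add_ramp(ks, b1 * (1 - (k1 - ks) / delta_n1), b1)
      }
      if (delta_n2 >= 1 && b2 != 0) {
        ks <- (k2 + 1):(k2 + delta_n2)
        add_ramp(ks, b2 * (1 - (ks - k2) / delta_n2), b2)
      }
    }
    clip <- abs(ramp_sum) > ramp_cap
    ramp_sum[clip] <- sign(ramp_sum[clip]) * ramp_cap[clip]
    orow <- orow + ramp_sum
    out[a, ] <- orow
  }
  sinogram(out, diff$geometry)
}

#' High-frequency suppression of an image
#'
#' The reconstruction of the smoothed difference sinogram still carries
#' high-frequency noise from the trace boundaries (and, on scanner data,
#' from registration error), so the artifact image is low-pass filtered
#' before subtraction.  Realized as a Gaussian blur of width `sigma`
#' pixels.
#'
#' @param image a [slice_image()] or matrix.
#' @param sigma Gaussian width in pixels.
#' @return same type as the input.
#' @export
hff_smooth <- function(image, sigma = 1.5) {
  if (inherits(image, "slice_image")) {
    out <- image
    out$values <- .gblur(image$values, sigma)
    return(out)
  }
  .gblur(image, sigma)
}

.gblur <- function(v, sigma) {
  if (sigma <= 0) return(v)
  matrix(as.numeric(EBImage::gblur(v, sigma = sigma)), nrow(v), ncol(v))
}

#' Reconstruct the artifact image
#'
#' FBP of the smoothed metal-trace difference sinogram followed by
#' high-frequency suppression: the image-domain estimate of the streak and
#' shading content attributable to the metal.
#'
#' @param p_interp a [smooth_boundaries()] sinogram.
#' @param geometry a [scan_geometry()].
#' @param hff_sigma_mm Gaussian low-pass width in mm.
#' @param filter_name FBP filter.
#' @return a [slice_image()] with modality `"artifact"`.
#' @export
reconstruct_artifact <- function(p_interp, geometry = p_interp$geometry,
                                 hff_sigma_mm = 1.5, filter_name = "ramp") {
  if (!any(p_interp$values != 0)) { # zero sinogram -> exactly zero artifact
    return(slice_image(matrix(0, geometry$image_shape[1], geometry$image_shape[2]),
                       geometry$pixel_spacing, "artifact"))
  }
  img <- .fbp_matrix(p_interp$values, geometry, filter_name)
  slice_image(.gblur(img, hff_sigma_mm / geometry$pixel_spacing),
              geometry$pixel_spacing, "artifact")
}

#' One correction pass
#'
#' Composes the correction chain: metal trace, kV/template sinogram
#' difference on the trace, boundary ramps, artifact reconstruction with
#' high-frequency suppression, and subtraction from the ORIGINAL kV image.
#' Pixels inside the metal mask are then restored from the kV image so the
#' implant stays visible for delineation.
#'
#' @param kv the original kV [slice_image()].
#' @param template a [build_template()] image.
#' @param metal a [metal_mask()].
#' @param geometry a [scan_geometry()].
#' @param config a [mar_config()].
#' @param kv_sino optional precomputed `forward_project(kv, geometry)`.
#' @param trace optional precomputed [metal_trace()].
#' @return the corrected [slice_image()]; the artifact estimate is attached
#'   as `attr(, "artifact")`.
#' @export
correct_once <- function(kv, template, metal, geometry, config = mar_config(),
                         kv_sino = NULL, trace = NULL) {
  check_image_geometry(kv, geometry)
  check_image_geometry(template, geometry)
  if (is.null(trace)) trace <- metal_trace(metal, geometry, config$trace_epsilon)
  zero_art <- slice_image(matrix(0, nrow(kv$values), ncol(kv$values)),
                          kv$pixel_spacing, "artifact")
  if (!any(trace$mask)) { # empty trace: exact identity
    out <- slice_image(kv$values, kv$pixel_spacing, "corrected")
    attr(out, "artifact") <- zero_art
    return(out)
  }
  if (is.null(kv_sino)) kv_sino <- forward_project(kv, geometry)
  tmpl_sino <- forward_project(template, geometry)
  d <- sinogram_difference(kv_sino, tmpl_sino, trace)
  p_interp <- smooth_boundaries(d, trace, config$delta_n1, config$delta_n2)
  artifact <- reconstruct_artifact(p_interp, geometry, config$hff_sigma_mm,
                                   config$filter_name)
  corr <- kv$values - artifact$values
  corr[metal$mask] <- kv$values[metal$mask]
  out <- slice_image(corr, kv$pixel_spacing, "corrected")
  attr(out, "artifact") <- artifact
  out
}

#' Iterative MV-prior metal artifact reduction
#'
#' The full correction loop.  The tissue masks come from one block-wise
#' Otsu segmentation of the MV prior and the metal mask from one threshold
#' segmentation of the kV image; both are held fixed.  Each iteration
#' rebuilds the template from the CURRENT corrected image (iteration 1:
#' from the kV image itself) -- only the regional fill means can change --
#' and applies [correct_once()] to the ORIGINAL kV image with the updated
#' template, so artifact estimates are never compounded on compounded
#' images.
#'
#' @param kv,mv co-registered kV and MV [slice_image()]s of the same shape.
#' @param geometry a [scan_geometry()].
#' @param config a [mar_config()].
#' @param ground_truth optional reference [slice_image()]; if given,
#'   per-iteration NRMSD over non-metal pixels is recorded in diagnostics.
#' @param masks,metal optional precomputed segmentations (defaults are
#'   computed from `mv` / `kv`).
#' @return an object of class `mar_result`: `corrected` (final
#'   [slice_image()]), `artifacts` and `templates` (per-iteration lists),
#'   `masks`, `metal`, `diagnostics` (data.frame with per-iteration NRMSD
#'   when a ground truth is supplied), `config`.
#' @export
iterate_mar <- function(kv, mv, geometry, config = mar_config(),
                        ground_truth = NULL, masks = NULL, metal = NULL) {
  if (!identical(dim(kv$values), dim(mv$values))) {
    abort_mvmar("kV and MV images must be co-registered (same shape)",
                "mvmar_geometry_error")
  }
  check_image_geometry(kv, geometry)
  if (config$iterations < 1) abort_mvmar("iterations must be >= 1", "mvmar_validation_error")
  if (is.null(metal)) {
    metal <- segment_metal(kv, config$metal_threshold_hu, config$min_metal_area)
  }
  if (is.null(masks)) {
    masks <- blockwise_segment(mv, block = config$block, metal_hint = metal)
  }
  trace <- metal_trace(metal, geometry, config$trace_epsilon)
  kv_sino <- if (any(trace$mask)) forward_project(kv, geometry) else NULL

  current <- kv
  artifacts <- vector("list", config$iterations)
  templates <- vector("list", config$iterations)
  diag_rows <- vector("list", config$iterations)
  nonmetal <- !metal$mask
  for (it in seq_len(config$iterations)) {
    templates[[it]] <- build_template(current, masks, iteration = it)
    current <- correct_once(kv, templates[[it]], metal, geometry, config,
                            kv_sino = kv_sino, trace = trace)
    artifacts[[it]] <- attr(current, "artifact")
    nr <- if (!is.null(ground_truth)) {
      sqrt(sum((current$values[nonmetal] - ground_truth$values[nonmetal])^2) /
             sum(ground_truth$values[nonmetal]^2))
    } else NA_real_
    diag_rows[[it]] <- data.frame(iteration = it, nrmsd_vs_truth = nr)
    log_msg("iteration %d: fill means M2=%.1f M3=%.1f%s", it,
            attr(templates[[it]], "fill_means")[1],
            attr(templates[[it]], "fill_means")[2],
            if (is.na(nr)) "" else sprintf(", NRMSD=%.4f", nr))
  }
  structure(list(corrected = current, artifacts = artifacts,
                 templates = templates, masks = masks, metal = metal,
                 diagnostics = do.call(rbind, diag_rows), config = config),
            class = "mar_result")
}

#' @export
print.mar_result <- function(x, ...) {
  cat(sprintf("<mar_result> %d iterations, %d metal px\n",
              x$config$iterations, sum(x$metal$mask)))
  if (!all(is.na(x$diagnostics$nrmsd_vs_truth))) print(x$diagnostics)
  invisible(x)
}
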