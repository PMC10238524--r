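#' Regions of interest
#'
#' Circular and rectangular pixel regions used by the image-quality
#' metrics.  Coordinates are pixel `c(row, col)`; a ROI must lie fully
#' inside the image and contain at least 4 pixels.
#'
#' @param center pixel `c(row, col)` of the circle center / rectangle center.
#' @param radius circle radius in pixels.
#' @param size rectangle `c(height, width)` in pixels.
#' @param label ROI name.
#' @return an object of class `roi`.
#' @export
roi_circle <- function(center, radius, label = "roi") {
  structure(list(shape = "circle", center = center, radius = radius,
                 label = label), class = "roi")
}

#' @rdname roi_circle
#' @export
roi_rect <- function(center, size, label = "roi") {
  structure(list(shape = "rect", center = center, size = size,
                 label = label), class = "roi")
}

#' Logical pixel mask of a ROI
#'
#' @param roi a [roi_circle()] / [roi_rect()].
#' @param shape image `c(rows, cols)`.
#' @return logical matrix.
#' @export
roi_mask <- function(roi, shape) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  m <- if (roi$shape == "circle") {
    (rr - roi$center[1])^2 + (cc - roi$center[2])^2 <= roi$radius^2
  } else {
    abs(rr - roi$center[1]) <= roi$size[1] / 2 &
      abs(cc - roi$center[2]) <= roi$size[2] / 2
  }
  out_of_bounds <- switch(roi$shape,
    circle = roi$center[1] - roi$radius < 1 || roi$center[1] + roi$radius > shape[1] ||
      roi$center[2] - roi$radius < 1 || roi$center[2] + roi$radius > shape[2],
    rect = roi$center[1] - roi$size[1] / 2 < 1 || roi$center[1] + roi$size[1] / 2 > shape[1] ||
      roi$center[2] - roi$size[2] / 2 < 1 || roi$center[2] + roi$size[2] / 2 > shape[2])
  if (out_of_bounds) {
    abort_mvmar(sprintf("ROI '%s' extends outside the image", roi$label),
                "mvmar_validation_error")
  }
  if (sum(m) < 4) {
    abort_mvmar(sprintf("ROI '%s' has fewer than 4 pixels", roi$label),
                "mvmar_validation_error")
  }
  m
}

#' Mean CT value and noise (SD) over a ROI
#'
#' The mean measures CT-value accuracy; the population standard deviation
#' of the ROI pixel values is the noise measure.
#'
#' @param img a [slice_image()].
#' @param roi a [roi_circle()] / [roi_rect()].
#' @return `c(mean, sd)` in HU.
#' @export
roi_mean_and_noise <- function(img, roi) {
  v <- img$values[roi_mask(roi, dim(img$values))]
  n <- length(v)
  m <- mean(v)
  c(mean = m, sd = sqrt(sum((v - m)^2) / n))
}

#' Mean relative error of ROI means
#'
#' `|mean_cor - mean_ref| / |mean_ref|`, the CT-value accuracy measure;
#' applied to the ROI mean values of the corrected and reference images.
#'
#' @param mean_cor,mean_ref ROI mean CT values (HU).
#' @return dimensionless ratio.
#' @examples
#' mre(49.6, 48.0) # 0.03 at 2 dp
#' @export
mre <- function(mean_cor, mean_ref) {
  if (mean_ref == 0) {
    abort_mvmar("MRE is undefined for a zero reference mean", "mvmar_undefined_metric")
  }
  abs(mean_cor - mean_ref) / abs(mean_ref)
}

#' Normalized root-mean-square deviation over a ROI
#'
#' `sqrt(sum((cor - ref)^2) / sum(ref^2))` over the ROI pixels.
#'
#' @param cor,ref [slice_image()]s of equal shape.
#' @param roi a ROI, or `NULL` for the whole image.
#' @return dimensionless ratio.
#' @export
nrmsd <- function(cor, ref, roi = NULL) {
  m <- .roi_values(cor, ref, roi)
  denom <- sum(m$ref^2)
  if (denom == 0) {
    abort_mvmar("NRMSD is undefined for a zero-energy reference", "mvmar_undefined_metric")
  }
  sqrt(sum((m$cor - m$ref)^2) / denom)
}

#' Mean absolute deviation over a ROI
#'
#' `sum(|cor - ref|) / N` over the N ROI pixels, in HU.
#'
#' @inheritParams nrmsd
#' @return HU value.
#' @export
mad_roi <- function(cor, ref, roi = NULL) {
  m <- .roi_values(cor, ref, roi)
  mean(abs(m$cor - m$ref))
}

.roi_values <- function(cor, ref, roi) {
  if (!identical(dim(cor$values), dim(ref$values))) {
    abort_mvmar("image shapes differ", "mvmar_geometry_error")
  }
  if (is.null(roi)) {
    list(cor = as.vector(cor$values), ref = as.vector(ref$values))
  } else {
    m <- roi_mask(roi, dim(cor$values))
    list(cor = cor$values[m], ref = ref$values[m])
  }
}

#' Benchmark metrics report
#'
#' The full per-(method, ROI) metric grid against a reference image: mean
#' CT value, noise SD, MRE, NRMSD and MAD, plus the reference ROI mean.
#' MRE values are carried at full precision and additionally rounded to 2
#' decimals (`mre_2dp`) for report formatting.
#'
#' @param methods named list of corrected [slice_image()]s (include the
#'   uncorrected image under a name like `"original"` for comparison).
#' @param reference the reference [slice_image()].
#' @param rois named list of ROIs.
#' @return a `data.frame` of class `metrics_report`.
#' @export
benchmark_report <- function(methods, reference, rois) {
  if (is.null(names(methods)) || any(names(methods) == "")) {
    abort_mvmar("methods must be a named list", "mvmar_validation_error")
  }
  rows <- list()
  for (mn in names(methods)) {
    img <- methods[[mn]]
    for (rn in names(rois)) {
      roi <- rois[[rn]]
      ms <- roi_mean_and_noise(img, roi)
      rs <- roi_mean_and_noise(reference, roi)
      mre_v <- if (rs[1] != 0) mre(ms[1], rs[1]) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        method = mn, roi = rn, n_pixels = sum(roi_mask(roi, dim(img$values))),
        mean_hu = unname(ms[1]), noise_hu = unname(ms[2]),
        ref_mean_hu = unname(rs[1]), ref_noise_hu = unname(rs[2]),
        mre = unname(mre_v), mre_2dp = round(unname(mre_v), 2),
        nrmsd = nrmsd(img, reference, roi),
        mad = mad_roi(img, reference, roi)
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' Write / read a metrics report
#'
#' CSV serialization round-trips bit-identically on the formatted values;
#' JSON carries the same rows.
#'
#' @param report a [benchmark_report()].
#' @param path output path; the extension (`.csv` or `.json`) picks the
#'   format.
#' @return `read_report()` returns the report `data.frame`.
#' @export
write_report <- function(report, path) {
  fmt <- tools::file_ext(path)
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  if (fmt == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (fmt == "json") {
    jsonlite::write_json(df, path, digits = NA, dataframe = "rows")
  } else {
    abort_mvmar(sprintf("unknown report format '%s'", fmt), "mvmar_io_error")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  fmt <- tools::file_ext(path)
  out <- if (fmt == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (fmt == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    abort_mvmar(sprintf("unknown report format '%s'", fmt), "mvmar_io_error")
  }
  class(out) <- c("metrics_report", "data.frame")
  out
}
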