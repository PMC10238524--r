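#' Two-threshold Otsu (maximum between-class variance)
#'
#' Finds the threshold pair splitting a gray-value sample into three
#' classes (low / medium / high) by maximizing the between-class variance
#' over a 256-bin histogram of the sample's range.  Among maximizing pairs
#' the lexicographically smallest `(t_low, t_high)` is returned, so the
#' output is deterministic.  Thresholds are bin-edge values with
#' `t_low < t_high`; classify as low `x <= t_low`, medium
#' `t_low < x <= t_high`, high `x > t_high`.
#'
#' @param values numeric sample of gray values (at least 3 distinct values).
#' @param n_bins histogram resolution.
#' @return `c(t_low, t_high)`.
#' @export
otsu_two_thresholds <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 3) {
    abort_mvmar("need >= 3 distinct values for a 3-class split",
                "mvmar_degenerate")
  }
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  W <- cumsum(counts)
  S <- cumsum(counts * mids)
  n <- W[n_bins]; total <- S[n_bins]
  # class sums for every ordered split (i < j): [1..i], (i..j], (j..B]
  w1 <- W; s1 <- S
  # between-class variance = sum_c s_c^2 / w_c  - const; vectorized over j per i
  best <- -Inf; best_ij <- c(NA, NA)
  for (i in seq_len(n_bins - 1)) {
    if (w1[i] == 0) next
    j <- seq(i + 1, n_bins)
    jj <- j[j < n_bins]
    if (length(jj) == 0) next
    w2 <- W[jj] - w1[i]; s2 <- S[jj] - s1[i]
    w3 <- n - W[jj]; s3 <- total - S[jj]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    crit <- rep(-Inf, length(jj))
    crit[ok] <- s1[i]^2 / w1[i] + s2[ok]^2 / w2[ok] + s3[ok]^2 / w3[ok]
    k <- which.max(crit) # first max -> smallest j for this i
    if (is.finite(crit[k]) &&
        (!is.finite(best) || crit[k] > best + 1e-12 * max(1, abs(best)))) {
      best <- crit[k]; best_ij <- c(i, jj[k])
    }
  }
  if (!is.finite(best)) {
    abort_mvmar("histogram too degenerate for a 3-class split", "mvmar_degenerate")
  }
  c(t_low = edges[best_ij[1] + 1], t_high = edges[best_ij[2] + 1])
}

#' Disjoint tissue masks
#'
#' Container for the three density classes of the prior segmentation:
#' `m1` high density (bone + metal), `m2` medium density (soft tissue),
#' `m3` low density (cavity and air).  The masks are pairwise disjoint and
#' cover every pixel.
#'
#' @param m1,m2,m3 logical matrices.
#' @param thresholds optional named thresholds recorded for provenance.
#' @return an object of class `tissue_masks`.
#' @export
tissue_masks <- function(m1, m2, m3, thresholds = NULL) {
  if (!identical(dim(m1), dim(m2)) || !identical(dim(m1), dim(m3))) {
    abort_mvmar("mask shapes differ", "mvmar_validation_error")
  }
  total <- m1 + m2 + m3
  if (any(total != 1)) {
    abort_mvmar("tissue masks must partition the image (disjoint, covering)",
                "mvmar_validation_error")
  }
  structure(list(m1 = m1, m2 = m2, m3 = m3, thresholds = thresholds),
            class = "tissue_masks")
}

classify_three <- function(values, t_low, t_high) {
  lab <- matrix(2L, nrow(values), ncol(values))
  lab[values <= t_low] <- 3L  # low density
  lab[values > t_high] <- 1L  # high density
  lab
}

#' Block-wise multi-threshold Otsu segmentation of the MV prior
#'
#' Divides the image into `block x block` pixel blocks (trailing partial
#' blocks at the edges are processed as their own smaller blocks), runs the
#' two-threshold Otsu split inside each block, and splices the block
#' results into one high/medium/low-density mask set.  Local thresholding
#' adapts to the residual shading of the MV image; splicing is made robust
#' by mapping each local class to a tissue label through its class MEAN
#' compared against the global image thresholds, so a block containing a
#' single noisy tissue does not scatter noise pixels into the wrong mask.
#' Blocks whose value range is below `degenerate_range` (near-constant)
#' fall back to the global thresholds directly.
#'
#' @param mv_image a [slice_image()] (the MV prior).
#' @param block block edge length in pixels (>= 2).
#' @param metal_hint optional [segment_metal()] mask; hinted pixels are
#'   forced into the high-density class and excluded from threshold
#'   estimation (metal gray values are extreme outliers that would
#'   otherwise capture the high threshold and push bone into the
#'   medium-density class).
#' @param degenerate_range HU range below which a block is treated as
#'   uniform.
#' @return a [tissue_masks()] object.
#' @export
blockwise_segment <- function(mv_image, block = 8, metal_hint = NULL,
                              degenerate_range = 10) {
  if (block < 2) abort_mvmar("block must be >= 2", "mvmar_validation_error")
  v <- mv_image$values
  nr <- nrow(v); nc <- ncol(v)
  hint <- if (is.null(metal_hint)) {
    matrix(FALSE, nr, nc)
  } else metal_hint$mask
  glob <- tryCatch(otsu_two_thresholds(v[!hint]), mvmar_degenerate = function(e) NULL)
  lab <- matrix(2L, nr, nc)
  if (is.null(glob)) {
    # whole image is (near-)constant: one class for everyone, chosen from
    # the CT meaning of its value
    m <- mean(v)
    lab[] <- if (m <= -500) 3L else if (m > 300) 1L else 2L
  } else {
    row_starts <- seq(1, nr, by = block)
    col_starts <- seq(1, nc, by = block)
    for (r0 in row_starts) {
      r1 <- min(r0 + block - 1, nr)
      for (c0 in col_starts) {
        c1 <- min(c0 + block - 1, nc)
        bv <- v[r0:r1, c0:c1, drop = FALSE]
        bh <- hint[r0:r1, c0:c1, drop = FALSE]
        bsample <- bv[!bh]
        loc <- NULL
        if (length(bsample) > 2 && diff(range(bsample)) >= degenerate_range) {
          loc <- tryCatch(otsu_two_thresholds(bsample),
                          mvmar_degenerate = function(e) NULL)
        }
        if (is.null(loc)) {
          bl <- classify_three(bv, glob[1], glob[2])
        } else {
          bl <- classify_three(bv, loc[1], loc[2])
          # map local classes to tissue labels via class means vs global
          # thresholds
          for (k in 1:3) {
            if (any(bl == k)) {
              mk <- mean(bv[bl == k])
              bl[bl == k] <- if (mk <= glob[1]) 30L else if (mk > glob[2]) 10L else 20L
            }
          }
          bl <- bl / 10L
        }
        lab[r0:r1, c0:c1] <- bl
      }
    }
  }
  if (!is.null(metal_hint)) lab[metal_hint$mask] <- 1L
  tissue_masks(lab == 1L, lab == 2L, lab == 3L,
               thresholds = if (is.null(glob)) NULL else
                 c(global_low = unname(glob[1]), global_high = unname(glob[2])))
}

#' Metal mask
#'
#' Logical mask of metal pixels plus the threshold that produced it.
#'
#' @param mask logical matrix.
#' @param threshold_hu threshold used.
#' @param min_area minimum connected-component area kept.
#' @return an object of class `metal_mask`.
#' @export
metal_mask <- function(mask, threshold_hu = NA_real_, min_area = 0) {
  structure(list(mask = mask, threshold_hu = threshold_hu,
                 min_area = min_area), class = "metal_mask")
}

#' Threshold segmentation of metal in the kV image
#'
#' Pixels at or above `threshold_hu` (well above the bone range; metal
#' reconstructs in the thousands of HU) form the metal region; connected
#' components smaller than `min_area` pixels are removed as speckle.
#'
#' @param kv_image a [slice_image()].
#' @param threshold_hu metal threshold in HU.
#' @param min_area minimum component area in pixels.
#' @return a [metal_mask()].
#' @export
segment_metal <- function(kv_image, threshold_hu = 2500, min_area = 4) {
  m <- kv_image$values >= threshold_hu
  if (any(m) && min_area > 1) {
    comp <- EBImage::bwlabel(m * 1)
    sizes <- tabulate(comp[comp > 0])
    drop <- which(sizes < min_area)
    if (length(drop)) m[comp %in% drop] <- FALSE
  }
  metal_mask(m, threshold_hu, min_area)
}

#' Connected components of a metal mask
#'
#' @param metal a [metal_mask()].
#' @return integer label matrix (0 = background).
#' @export
metal_components <- function(metal) {
  matrix(as.integer(EBImage::bwlabel(metal$mask * 1)),
         nrow(metal$mask), ncol(metal$mask))
}
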