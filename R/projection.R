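#' Forward projection (parallel beam)
#'
#' Discrete line integrals of a slice image under a parallel-beam geometry.
#' The integral along each ray is evaluated ray-driven: the image is sampled
#' by bilinear interpolation at steps of one pixel spacing along the ray and
#' the samples are summed times the step length, so pixel values are treated
#' as a (piecewise-linear) function of position.  No offset is added: the
#' operator is linear, so constant offsets cancel in sinogram differences.
#'
#' @param image a [slice_image()] matching the geometry grid.
#' @param geometry a [scan_geometry()].
#' @return a [sinogram()] in value x mm units.
#' @examples
#' g <- scan_geometry(c(64, 64), n_angles = 30)
#' img <- slice_image(matrix(0, 64, 64))
#' range(forward_project(img, g)$values) # all zero
#' @export
forward_project <- function(image, geometry) {
  if (!inherits(image, "slice_image")) image <- slice_image(image)
  check_image_geometry(image, geometry)
  stopifnot_finite(image$values, "image")
  sinogram(.fp_matrix(image$values, geometry), geometry)
}

# Core projector on a plain matrix; reused by operators that project masks.
.fp_matrix <- function(v, geometry) {
  nr <- nrow(v); nc <- ncol(v)
  ps <- geometry$pixel_spacing; bs <- geometry$bin_spacing
  nb <- geometry$n_bins
  rmax <- sqrt(sum((c(nr, nc) * ps)^2)) / 2
  ns <- ceiling(2 * rmax / ps) + 1L
  svals <- seq(-rmax, rmax, length.out = ns)
  ds <- svals[2] - svals[1]
  tvals <- (seq_len(nb) - (nb + 1) / 2) * bs
  TT <- matrix(tvals, nb, ns)
  SS <- matrix(svals, nb, ns, byrow = TRUE)
  out <- matrix(0, geometry$n_angles, nb)
  for (a in seq_len(geometry$n_angles)) {
    th <- geometry$angles[a]
    ct <- cos(th); st <- sin(th)
    # sample point = t * (cos, sin) + s * (-sin, cos)
    x <- TT * ct - SS * st
    y <- TT * st + SS * ct
    cj <- x / ps + (nc + 1) / 2
    ri <- (nr + 1) / 2 - y / ps
    j0 <- floor(cj); i0 <- floor(ri)
    wj <- cj - j0; wi <- ri - i0
    ok <- j0 >= 1 & j0 < nc & i0 >= 1 & i0 < nr
    val <- numeric(length(x))
    idx <- (j0[ok] - 1L) * nr + i0[ok]
    wio <- wi[ok]; wjo <- wj[ok]
    val[ok] <- (1 - wio) * (1 - wjo) * v[idx] +
      wio * (1 - wjo) * v[idx + 1L] +
      (1 - wio) * wjo * v[idx + nr] +
      wio * wjo * v[idx + nr + 1L]
    out[a, ] <- .rowSums(val, nb, ns) * ds
  }
  out
}

# Band-limited Ram-Lak kernel sampled in the spatial domain (avoids the DC
# bias of a frequency-domain |f| ramp), returned as its real FFT response
# with the requested apodization window applied.
.fbp_filter <- function(npad, bs, filter_name) {
  k <- c(0:(npad / 2), (-npad / 2 + 1):(-1))
  h <- numeric(npad)
  h[1] <- 1 / (4 * bs^2)
  odd <- which(k %% 2 != 0)
  h[odd] <- -1 / (pi * k[odd] * bs)^2
  H <- Re(stats::fft(h))
  f <- abs(k) / npad # cycles per sample, up to 0.5
  win <- switch(filter_name,
    "ramp" = , "ram-lak" = rep(1, npad),
    "shepp-logan" = {
      w <- rep(1, npad); nz <- f > 0
      w[nz] <- sin(pi * f[nz]) / (pi * f[nz]); w
    },
    "hann" = 0.5 + 0.5 * cos(2 * pi * f),
    "cosine" = cos(pi * f),
    abort_mvmar(sprintf("unknown reconstruction filter '%s'", filter_name),
                "mvmar_config_error")
  )
  H * win
}

#' Filtered back-projection (FBP)
#'
#' Reconstructs a slice image from a parallel-beam sinogram by ramp
#' filtering each projection (FFT convolution with a band-limited Ram-Lak
#' kernel, optionally apodized) and back-projecting with linear detector
#' interpolation.  A zero sinogram reconstructs to an exactly zero image.
#'
#' @param sino a [sinogram()].
#' @param geometry a [scan_geometry()]; defaults to the sinogram's own.
#' @param filter_name one of `"ramp"` (Ram-Lak, default), `"shepp-logan"`,
#'   `"hann"`, `"cosine"`.
#' @param modality modality tag for the reconstructed [slice_image()].
#' @return a [slice_image()] in the units of `sino / mm`.
#' @export
back_project_fbp <- function(sino, geometry = sino$geometry,
                             filter_name = "ramp", modality = "unknown") {
  if (!inherits(sino, "sinogram")) abort_mvmar("sino must be a sinogram", "mvmar_validation_error")
  if (!identical(dim(sino$values), c(geometry$n_angles, geometry$n_bins))) {
    abort_mvmar("sinogram shape does not match geometry", "mvmar_geometry_error")
  }
  slice_image(.fbp_matrix(sino$values, geometry, filter_name),
              pixel_spacing = geometry$pixel_spacing, modality = modality)
}

.fbp_matrix <- function(p, geometry, filter_name = "ramp") {
  nr <- geometry$image_shape[1]; nc <- geometry$image_shape[2]
  nb <- geometry$n_bins
  ps <- geometry$pixel_spacing; bs <- geometry$bin_spacing
  npad <- 2^ceiling(log2(2 * nb))
  H <- .fbp_filter(npad, bs, filter_name)
  co <- grid_coords(geometry)
  Xv <- as.vector(co$x); Yv <- as.vector(co$y)
  acc <- numeric(nr * nc)
  cx <- (nb + 1) / 2
  for (a in seq_len(geometry$n_angles)) {
    row <- p[a, ]
    if (!any(row != 0)) next # zero projection contributes exactly zero
    q <- Re(stats::fft(stats::fft(c(row, numeric(npad - nb))) * H,
                       inverse = TRUE)) / npad * bs
    qpad <- c(0, q[seq_len(nb)], 0)
    th <- geometry$angles[a]
    u <- (Xv * cos(th) + Yv * sin(th)) / bs + cx
    i0 <- floor(u); w <- u - i0
    inside <- i0 >= 1 & i0 < nb
    i0c <- pmax(pmin(i0, nb), 0L)
    val <- qpad[i0c + 1L] * (1 - w) + qpad[i0c + 2L] * w
    val[!inside & !(i0 == 0 | i0 == nb)] <- 0
    acc <- acc + val
  }
  matrix(acc * pi / geometry$n_angles, nr, nc)
}
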