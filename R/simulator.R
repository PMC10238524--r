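#' Polychromatic scan of a material phantom
#'
#' Simulates the physics the artifact model rests on.  Per detector bin the
#' detected count is `N0 * sum_E w(E) * exp(-sum_path mu(E) * len)`
#' (Beer-Lambert under a discrete spectrum), optionally Poisson-perturbed,
#' floored at a configurable count before the log (photon starvation: a ray
#' absorbed almost completely carries no usable signal, which is the streak
#' mechanism), and returned as the log-transmission `-log(count / N0)`.
#' Path lengths per material come from forward projection of the material
#' indicator maps, so a single-energy spectrum with noise disabled
#' reproduces the plain line integral of the mu map exactly.
#'
#' @param labels a [rasterize_phantom()] grid.
#' @param spec the [phantom_spec()] the grid came from (for the material table).
#' @param spectrum an [xray_spectrum()].
#' @param geometry a [scan_geometry()] matching the grid.
#' @param seed RNG seed for the Poisson noise; `NULL` leaves the session RNG.
#' @param noise apply Poisson counting noise.
#' @param starvation_floor minimum detected count before the log.
#' @return a [sinogram()] of log-transmission values.
#' @export
polychromatic_scan <- function(labels, spec, spectrum, geometry,
                               seed = NULL, noise = TRUE,
                               starvation_floor = 1) {
  if (spectrum$n0 <= 0) abort_mvmar("n0 must be positive", "mvmar_validation_error")
  lens <- material_path_lengths(labels, geometry)
  trans <- matrix(0, geometry$n_angles, geometry$n_bins)
  for (e in seq_along(spectrum$energies)) {
    optical <- matrix(0, geometry$n_angles, geometry$n_bins)
    for (m in names(lens)) {
      mu <- material_mu(spec$materials, m, spectrum$energies[e])
      if (mu > 0) optical <- optical + mu * lens[[m]]
    }
    trans <- trans + spectrum$weights[e] * exp(-optical)
  }
  counts <- spectrum$n0 * trans
  if (noise) {
    counts <- with_seed(seed, matrix(
      stats::rpois(length(counts), lambda = pmin(counts, .Machine$integer.max / 2)),
      nrow(counts), ncol(counts)))
  }
  counts <- pmax(counts, starvation_floor)
  sinogram(-log(counts / spectrum$n0), geometry)
}

# Forward-project each material's indicator map -> mm of material per ray.
# Tiny negative interpolation dust is clipped at zero.
material_path_lengths <- function(labels, geometry) {
  levels <- attr(labels, "materials")
  out <- list()
  for (i in seq_along(levels)) {
    if (levels[i] == "air") next # mu contribution negligible along any path
    mask <- matrix(as.numeric(unclass(labels) == i), nrow(labels), ncol(labels))
    if (!any(mask > 0)) next
    out[[levels[i]]] <- pmax(.fp_matrix(mask, geometry), 0)
  }
  out
}

# Water beam-hardening precorrection, the standard scanner-side water
# calibration: map a measured polychromatic log-transmission p to the
# water-equivalent path length t solving p_poly(t) = p, then rescale to the
# monochromatic integral mu_w_eff * t.  Pure-water paths come out exact;
# bone and metal keep their hardening residual, which is the artifact.
water_precorrection_fn <- function(materials, spectrum, t_max = 500) {
  tgrid <- seq(0, t_max, by = 1)
  muw_e <- material_mu(materials, "water", spectrum$energies)
  p_poly <- vapply(tgrid, function(t) {
    -log(sum(spectrum$weights * exp(-muw_e * t)))
  }, numeric(1))
  muw_eff <- sum(spectrum$weights * muw_e)
  slope_end <- (p_poly[length(p_poly)] - p_poly[length(p_poly) - 1])
  function(p) {
    t <- stats::approx(p_poly, tgrid, xout = pmin(p, max(p_poly)), rule = 2)$y
    over <- p > max(p_poly)
    if (any(over)) t[over] <- t_max + (p[over] - max(p_poly)) / slope_end
    muw_eff * t
  }
}

#' Simulate a co-registered kV / MV scan pair with ground truth
#'
#' Runs the polychromatic scanner model once at a diagnostic kV spectrum
#' and once at a megavoltage spectrum on the same phantom, reconstructs
#' both with FBP, and calibrates to HU via the water and air effective
#' attenuations of each spectrum.  The kV chain applies the standard water
#' beam-hardening precorrection, so residual bone/metal hardening plus
#' photon starvation produce the streak and shading artifacts; at MV the
#' metal is nearly transparent and the image is close to artifact-free.
#' The ground truths are noiseless monochromatic reconstructions at each
#' spectrum's effective attenuation.  All grids share shape and spacing:
#' the pair is co-registered by construction.
#'
#' @param spec a [phantom_spec()].
#' @param kv_spectrum,mv_spectrum [xray_spectrum()] models.
#' @param geometry a [scan_geometry()]; defaults to one matching the
#'   phantom grid with `max(shape)` angles (wait-free default for tests).
#' @param seed integer seed; the full ScanPair is a deterministic function
#'   of (spec, spectra, geometry, seed).
#' @param noise apply Poisson noise.
#' @return an object of class `scan_pair` with elements `kv`, `mv`,
#'   `ground_truth_kv`, `ground_truth_mv`, `metal_truth` (logical grid),
#'   `labels`, `geometry`, `seed`.
#' @export
simulate_scan_pair <- function(spec,
                               kv_spectrum = mvmar::kv_spectrum(),
                               mv_spectrum = mvmar::mv_spectrum(),
                               geometry = NULL, seed = 1, noise = TRUE) {
  if (is.null(geometry)) {
    geometry <- scan_geometry(spec$shape, n_angles = max(spec$shape),
                              pixel_spacing = spec$pixel_spacing)
  }
  labels <- rasterize_phantom(spec)
  lens <- material_path_lengths(labels, geometry)
  mats <- spec$materials

  recon_hu <- function(p_sino, spectrum, modality) {
    muw <- effective_mu(mats, "water", spectrum)
    mua <- effective_mu(mats, "air", spectrum)
    mu_img <- .fbp_matrix(p_sino, geometry)
    slice_image(mu_to_hu(mu_img, muw, mua), geometry$pixel_spacing, modality)
  }
  truth_sino <- function(spectrum) {
    p <- matrix(0, geometry$n_angles, geometry$n_bins)
    for (m in names(lens)) p <- p + effective_mu(mats, m, spectrum) * lens[[m]]
    p
  }

  kv_raw <- polychromatic_scan(labels, spec, kv_spectrum, geometry,
                               seed = seed, noise = noise)
  precorrect <- water_precorrection_fn(mats, kv_spectrum)
  kv_p <- matrix(precorrect(as.vector(kv_raw$values)),
                 geometry$n_angles, geometry$n_bins)
  kv <- recon_hu(kv_p, kv_spectrum, "kV")

  mv_raw <- polychromatic_scan(labels, spec, mv_spectrum, geometry,
                               seed = if (is.null(seed)) NULL else seed + 104729L,
                               noise = noise)
  mv_pre <- water_precorrection_fn(mats, mv_spectrum)
  mv_p <- matrix(mv_pre(as.vector(mv_raw$values)),
                 geometry$n_angles, geometry$n_bins)
  mv <- recon_hu(mv_p, mv_spectrum, "MV")

  gt_kv <- recon_hu(truth_sino(kv_spectrum), kv_spectrum, "kV")
  gt_mv <- recon_hu(truth_sino(mv_spectrum), mv_spectrum, "MV")

  metal_names <- unique(mats$material[mats$tissue_class == "metal"])
  metal_truth <- matrix(attr(labels, "materials")[unclass(labels)] %in% metal_names,
                        nrow(labels), ncol(labels))

  structure(list(kv = kv, mv = mv, ground_truth_kv = gt_kv,
                 ground_truth_mv = gt_mv, metal_truth = metal_truth,
                 labels = labels, geometry = geometry, seed = seed),
            class = "scan_pair")
}

#' @export
print.scan_pair <- function(x, ...) {
  cat(sprintf("<scan_pair> %dx%d @ %.3g mm, %d metal px, seed %s\n",
              nrow(x$kv$values), ncol(x$kv$values), x$kv$pixel_spacing,
              sum(x$metal_truth), format(x$seed)))
  invisible(x)
}
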