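#' Load the material attenuation table
#'
#' Reads a table of linear attenuation coefficients mu(E) (1/mm) on a shared
#' energy grid for the simulator's materials.  The packaged default covers
#' air, water, soft tissue, lung-equivalent low-density material, cortical
#' bone, titanium and a dental-amalgam-like alloy on 40-120 keV plus two
#' megavoltage-range points, populated from standard published
#' mass-attenuation data.  Values are approximate; the simulator's contract
#' depends on their orderings and ratios, not on exact magnitudes.
#'
#' @param path CSV with columns `material`, `tissue_class`, `energy_kev`,
#'   `mu_per_mm`; defaults to the packaged table.
#' @return a `data.frame` of class `material_table`.
#' @export
load_materials <- function(path = system.file("extdata", "materials.csv",
                                              package = "mvmar")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("material", "tissue_class", "energy_kev", "mu_per_mm")
  if (!all(need %in% names(tab))) {
    abort_mvmar("material table must have columns material, tissue_class, energy_kev, mu_per_mm",
                "mvmar_validation_error")
  }
  for (m in unique(tab$material)) {
    sub <- tab[tab$material == m, ]
    sub <- sub[order(sub$energy_kev), ]
    if (m != "air" && any(sub$mu_per_mm <= 0)) {
      abort_mvmar(sprintf("material '%s' has non-positive attenuation", m),
                  "mvmar_validation_error")
    }
    if (any(diff(sub$mu_per_mm) > 0)) {
      abort_mvmar(sprintf("material '%s' attenuation must be non-increasing with energy", m),
                  "mvmar_validation_error")
    }
  }
  class(tab) <- c("material_table", "data.frame")
  tab
}

#' Linear attenuation of a material at given energies
#'
#' Linear interpolation of the material table in energy (constant
#' extrapolation beyond the grid).
#'
#' @param materials a [load_materials()] table.
#' @param material material name.
#' @param energies energies in keV.
#' @return mu values in 1/mm.
#' @export
material_mu <- function(materials, material, energies) {
  sub <- materials[materials$material == material, ]
  if (nrow(sub) == 0) {
    abort_mvmar(sprintf("unknown material '%s'", material), "mvmar_validation_error")
  }
  stats::approx(sub$energy_kev, sub$mu_per_mm, xout = energies, rule = 2)$y
}

#' X-ray spectrum model
#'
#' A discrete fluence spectrum: energy-bin centers, relative weights
#' (normalized to sum to one) and the unattenuated photon count per
#' detector bin.
#'
#' @param energies bin centers in keV, strictly increasing.
#' @param weights nonnegative relative fluence weights.
#' @param n0 incident photon count per detector bin.
#' @return an object of class `xray_spectrum`.
#' @export
xray_spectrum <- function(energies, weights, n0) {
  if (any(weights < 0) || sum(weights) <= 0) {
    abort_mvmar("spectrum weights must be nonnegative with positive sum",
                "mvmar_validation_error")
  }
  if (n0 <= 0) abort_mvmar("n0 must be positive", "mvmar_validation_error")
  if (is.unsorted(energies, strictly = TRUE)) {
    abort_mvmar("spectrum energies must be strictly increasing", "mvmar_validation_error")
  }
  structure(list(energies = energies, weights = weights / sum(weights),
                 n0 = n0), class = "xray_spectrum")
}

#' Default diagnostic kV spectrum
#'
#' Nine bins over 40-120 keV with a bremsstrahlung-like hump: wide enough
#' in energy to produce beam hardening through bone and metal.
#'
#' @param n0 incident photons per detector bin.
#' @return an `xray_spectrum`.
#' @export
kv_spectrum <- function(n0 = 2e5) {
  en <- seq(40, 120, by = 10)
  w <- en * (140 - en) # crude bremsstrahlung hump peaking near 70 keV
  xray_spectrum(en, w / sum(w), n0)
}

#' Default megavoltage beam spectrum
#'
#' Two bins in the Compton-dominated region standing in for the detected
#' spectrum of a 1.5 MV imaging beam; attenuation there is nearly
#' material-ordering-preserving and metal transmission is high, which is
#' what removes metal artifacts at MV energies.
#'
#' @param n0 incident photons per detector bin.
#' @return an `xray_spectrum`.
#' @export
mv_spectrum <- function(n0 = 5e5) {
  xray_spectrum(c(500, 1000), c(0.6, 0.4), n0)
}

# Spectrum-weighted effective attenuation (the thin-path limit of the
# polychromatic log-transmission slope).
effective_mu <- function(materials, material, spectrum) {
  sum(spectrum$weights * material_mu(materials, material, spectrum$energies))
}

#' Reference Hounsfield value of a material under a spectrum
#'
#' HU computed from effective attenuations with water at 0 and air at
#' -1000, i.e. the value an ideal scanner at this spectrum's effective
#' energy would assign.
#'
#' @inheritParams material_mu
#' @param spectrum an [xray_spectrum()].
#' @return HU value.
#' @export
material_hu <- function(materials, material, spectrum) {
  mu <- effective_mu(materials, material, spectrum)
  muw <- effective_mu(materials, "water", spectrum)
  mua <- effective_mu(materials, "air", spectrum)
  1000 * (mu - muw) / (muw - mua)
}

mu_to_hu <- function(mu, muw, mua) 1000 * (mu - muw) / (muw - mua)
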