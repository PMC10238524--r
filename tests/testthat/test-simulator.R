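test_that("rasterization covers analytic areas and honors painter's order", {
  mats <- load_materials()
  # empty primitive list -> all air
  empty <- phantom_spec(c(32, 32), 1, list(), mats)
  g0 <- rasterize_phantom(empty)
  expect_true(all(attr(g0, "materials")[unclass(g0)] == "air"))
  # centered ellipse of water: pixel count within 2% of pi * a * b
  spec <- phantom_spec(c(128, 128), 1,
                       list(phantom_ellipse(c(0, 0), c(40, 25), "water")), mats)
  g1 <- rasterize_phantom(spec)
  n_water <- sum(attr(g1, "materials")[unclass(g1)] == "water")
  expect_equal(n_water, pi * 40 * 25, tolerance = 0.02)
  # overlap carries the later label
  spec2 <- phantom_spec(c(64, 64), 1, list(
    phantom_ellipse(c(0, 0), c(20, 20), "water"),
    phantom_rect(c(10, 0), c(20, 8), "bone")
  ), mats)
  g2 <- rasterize_phantom(spec2)
  lab <- attr(g2, "materials")[unclass(g2)]
  center_right <- matrix(lab, 64, 64)[33, 43] # inside both primitives
  expect_identical(center_right, "bone")
  expect_error(
    phantom_spec(c(64, 64), 1, list(phantom_ellipse(c(0, 0), c(5, 5), "kryptonite")), mats),
    class = "mvmar_validation_error")
})

test_that("single-energy noiseless scan collapses to the line integral", {
  mats <- load_materials()
  spec <- phantom_spec(c(64, 64), 2,
                       list(phantom_ellipse(c(0, 0), c(40, 30), "water")), mats)
  labels <- rasterize_phantom(spec)
  geom <- scan_geometry(c(64, 64), n_angles = 32, pixel_spacing = 2)
  sp <- xray_spectrum(70, 1, 1e5)
  p <- polychromatic_scan(labels, spec, sp, geom, noise = FALSE)
  mu <- material_mu(mats, "water", 70)
  water_map <- slice_image(matrix(as.numeric(
    attr(labels, "materials")[unclass(labels)] == "water"), 64, 64) * mu,
    pixel_spacing = 2)
  expect_equal(p$values, forward_project(water_map, geom)$values,
               tolerance = 1e-10)
})

test_that("metal rays lose more photons than metal-free rays at every angle", {
  mats <- load_materials()
  spec <- phantom_spec(c(64, 64), 2, list(
    phantom_ellipse(c(0, 0), c(50, 50), "water"),
    phantom_ellipse(c(10, 0), c(6, 6), "titanium")
  ), mats)
  labels <- rasterize_phantom(spec)
  geom <- scan_geometry(c(64, 64), n_angles = 24, pixel_spacing = 2)
  p <- polychromatic_scan(labels, spec, kv_spectrum(), geom, noise = FALSE)
  metal_map <- matrix(as.numeric(attr(labels, "materials")[unclass(labels)] == "titanium"),
                      64, 64)
  tr <- metal_trace(metal_mask(metal_map > 0), geom)
  for (a in seq_len(geom$n_angles)) {
    in_tr <- tr$mask[a, ]
    # the most attenuated ray of every view passes through the metal
    expect_gt(max(p$values[a, in_tr]), max(p$values[a, !in_tr]))
  }
})

test_that("polychromatic attenuation hardens with thickness", {
  # brute-force two-exponential model: -log(w1 e^{-m1 t} + w2 e^{-m2 t}) / t
  # decreases with t, i.e. the log-transmission is concave in path length
  w <- c(0.5, 0.5); mu <- c(0.03, 0.015)
  t <- seq(10, 300, by = 10)
  p <- vapply(t, function(tt) -log(sum(w * exp(-mu * tt))), numeric(1))
  eff <- p / t
  expect_true(all(diff(eff) < 0))
  expect_true(all(diff(p, differences = 2) < 1e-8)) # concavity
})

test_that("identical seeds reproduce the scan pair bit for bit", {
  spec <- fx_dental_spec(2)
  g <- fx_geometry()
  a <- simulate_scan_pair(spec, geometry = g, seed = 9)
  b <- simulate_scan_pair(spec, geometry = g, seed = 9)
  expect_identical(a$kv$values, b$kv$values)
  expect_identical(a$mv$values, b$mv$values)
  expect_identical(a$ground_truth_kv$values, b$ground_truth_kv$values)
  c_ <- simulate_scan_pair(spec, geometry = g, seed = 10)
  expect_false(identical(a$kv$values, c_$kv$values))
})

test_that("reconstructed HU are calibrated against water and air", {
  size <- 128
  spec <- cirs_like_phantom(c(size, size), metal_rod = FALSE)
  geom <- scan_geometry(spec$shape, n_angles = size,
                        pixel_spacing = spec$pixel_spacing)
  rois <- cirs_rois(spec$shape, spec$pixel_spacing)
  pair <- simulate_scan_pair(spec, geometry = geom, seed = 1)
  water <- roi_mean_and_noise(pair$kv, rois$water)
  air <- roi_mean_and_noise(pair$kv, rois$air)
  expect_lt(abs(water[["mean"]]), 15)
  expect_lt(abs(air[["mean"]] - (-1000)), 30)
})

test_that("metal artifacts dominate the no-metal error floor at kV", {
  pair2 <- fx_pair2()
  pair0 <- fx_pair0()
  rois <- fx_rois()
  floor_soft <- nrmsd(pair0$kv, pair0$ground_truth_kv, rois$soft)
  expect_lt(floor_soft, 0.55)
  with_metal <- nrmsd(pair2$kv, pair2$ground_truth_kv, rois$inter_metal)
  expect_gt(with_metal, 3.5 * floor_soft)
})

test_that("the MV image is nearly artifact-free where kV is corrupted", {
  pair <- fx_pair3()
  rois <- fx_rois()
  kv_err <- nrmsd(pair$kv, pair$ground_truth_kv, rois$inter_metal)
  mv_err <- nrmsd(pair$mv, pair$ground_truth_mv, rois$inter_metal)
  expect_lte(mv_err, 0.3 * kv_err)
})

test_that("MV gray values preserve the tissue density ordering", {
  pair <- fx_pair3()
  lab <- attr(pair$labels, "materials")[unclass(pair$labels)]
  m_bone <- mean(pair$mv$values[lab == "bone"])
  m_soft <- mean(pair$mv$values[lab == "soft_tissue"])
  m_air <- mean(pair$mv$values[lab == "air"])
  expect_gt(m_bone, m_soft)
  expect_gt(m_soft, m_air)
})

test_that("spectrum models are validated", {
  expect_error(xray_spectrum(c(40, 60), c(-1, 2), 1e5), class = "mvmar_validation_error")
  expect_error(xray_spectrum(c(40, 60), c(1, 1), 0), class = "mvmar_validation_error")
  sp <- kv_spectrum()
  expect_equal(sum(sp$weights), 1)
  # reference HU ordering under the diagnostic spectrum
  mats <- load_materials()
  expect_gt(material_hu(mats, "amalgam", sp), material_hu(mats, "titanium", sp))
  expect_gt(material_hu(mats, "titanium", sp), material_hu(mats, "bone", sp))
  expect_gt(material_hu(mats, "bone", sp), material_hu(mats, "soft_tissue", sp))
  expect_equal(material_hu(mats, "water", sp), 0)
})
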