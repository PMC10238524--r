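# analytic shadow interval of a disk at one angle: the disk's center
# projects to t0 = cx cos + cy sin and shadows [t0 - r, t0 + r]
disk_shadow_bins <- function(center, radius, th, geometry) {
  t0 <- center[1] * cos(th) + center[2] * sin(th)
  cx <- (geometry$n_bins + 1) / 2
  c(floor((t0 - radius) / geometry$bin_spacing + cx),
    ceiling((t0 + radius) / geometry$bin_spacing + cx))
}

test_that("metal trace of an empty mask is empty", {
  g <- scan_geometry(c(64, 64), n_angles = 20)
  tr <- metal_trace(metal_mask(matrix(FALSE, 64, 64)), g)
  expect_false(any(tr$mask))
  expect_true(all(vapply(tr$runs, nrow, 1L) == 0))
})

test_that("a centered disk produces one near-constant-width run per angle", {
  n <- 96
  g <- scan_geometry(c(n, n), n_angles = 48)
  img <- disk_image(n, radius_mm = 10, value = 1)
  tr <- metal_trace(metal_mask(img$values > 0), g)
  widths <- vapply(tr$runs, function(r) {
    expect_equal(nrow(r), 1)
    r[1, 2] - r[1, 1] + 1
  }, numeric(1))
  # oracle: geometric chord width 2 * r / bin_spacing, allowing the
  # rasterized disk edge (±0.5 px) plus the projector's bilinear footprint
  expect_lte(max(abs(widths - 2 * 10 / g$bin_spacing)), 3)
})

test_that("two separated disks merge exactly where their shadows overlap", {
  n <- 96
  g <- scan_geometry(c(n, n), n_angles = 48)
  c1 <- c(-18, 0); c2 <- c(18, 0); r <- 8
  v <- matrix(0, n, n)
  xs <- seq_len(n) - (n + 1) / 2
  X <- matrix(xs, n, n, byrow = TRUE); Y <- -t(X)
  v[(X - c1[1])^2 + (Y - c1[2])^2 <= r^2] <- 1
  v[(X - c2[1])^2 + (Y - c2[2])^2 <= r^2] <- 1
  tr <- metal_trace(metal_mask(v > 0), g)
  for (a in seq_len(g$n_angles)) {
    th <- g$angles[a]
    s1 <- disk_shadow_bins(c1, r, th, g)
    s2 <- disk_shadow_bins(c2, r, th, g)
    overlap <- min(s1[2], s2[2]) - max(s1[1], s2[1]) # bins of shadow overlap
    # runs widen by ~1 bin per side (rasterization + bilinear footprint),
    # so only angles safely away from tangency are decided
    want <- if (overlap >= 2) 1L else if (overlap <= -4) 2L else NA_integer_
    if (!is.na(want)) expect_equal(nrow(tr$runs[[a]]), want)
  }
})

test_that("sinogram difference is the cellwise difference inside the trace", {
  g <- scan_geometry(c(8, 8), n_angles = 2, n_bins = 12)
  kv_s <- sinogram(matrix(seq_len(24), 2, 12), g)
  tm_s <- sinogram(matrix(rev(seq_len(24)), 2, 12), g)
  mask <- matrix(FALSE, 2, 12); mask[1, 4:6] <- TRUE
  tr <- structure(list(mask = mask,
                       runs = list(cbind(k1 = 4L, k2 = 6L), cbind(k1 = integer(0), k2 = integer(0)))),
                  class = "metal_trace")
  d <- sinogram_difference(kv_s, tm_s, tr)
  want <- matrix(0, 2, 12)
  want[1, 4:6] <- kv_s$values[1, 4:6] - tm_s$values[1, 4:6]
  expect_equal(d$values, want)
  # identical sinograms -> zero difference
  expect_equal(sinogram_difference(kv_s, kv_s, tr)$values, matrix(0, 2, 12))
  # empty trace -> zero difference
  tr0 <- structure(list(mask = matrix(FALSE, 2, 12),
                        runs = rep(list(cbind(k1 = integer(0), k2 = integer(0))), 2)),
                   class = "metal_trace")
  expect_equal(sinogram_difference(kv_s, tm_s, tr0)$values, matrix(0, 2, 12))
})

test_that("boundary ramps interpolate linearly to zero", {
  g <- scan_geometry(c(8, 8), n_angles = 1, n_bins = 20)
  vals <- matrix(0, 1, 20)
  vals[1, 8:12] <- 6 # constant run value c
  mask <- vals != 0
  tr <- structure(list(mask = mask, runs = list(cbind(k1 = 8L, k2 = 12L))),
                  class = "metal_trace")
  sm <- smooth_boundaries(sinogram(vals, g), tr, delta_n1 = 2, delta_n2 = 2)
  expect_equal(sm$values[1, 7], 3)  # one bin out: c/2
  expect_equal(sm$values[1, 6], 0)  # two bins out: 0
  expect_equal(sm$values[1, 13], 3)
  expect_equal(sm$values[1, 14], 0)
  expect_equal(sm$values[1, 8:12], vals[1, 8:12]) # interior untouched
  expect_equal(sm$values[1, c(1:5, 16:20)], rep(0, 10))
  # all-zero difference stays zero
  z <- smooth_boundaries(sinogram(matrix(0, 1, 20), g), tr, 2, 2)
  expect_equal(z$values, matrix(0, 1, 20))
})

test_that("smoothed differences are continuous at run boundaries", {
  set.seed(41)
  g <- scan_geometry(c(8, 8), n_angles = 5, n_bins = 40)
  vals <- matrix(0, 5, 40)
  runs <- list()
  for (a in 1:5) {
    k1 <- sample(6:12, 1); k2 <- k1 + sample(3:8, 1)
    vals[a, k1:k2] <- rnorm(k2 - k1 + 1, 20, 5)
    runs[[a]] <- cbind(k1 = as.integer(k1), k2 = as.integer(k2))
  }
  mask <- vals != 0
  tr <- structure(list(mask = mask, runs = runs), class = "metal_trace")
  delta <- 4
  sm <- smooth_boundaries(sinogram(vals, g), tr, delta, delta)
  for (a in 1:5) {
    k1 <- runs[[a]][1, 1]; k2 <- runs[[a]][1, 2]
    ramp_step1 <- abs(vals[a, k1]) / delta
    ramp_step2 <- abs(vals[a, k2]) / delta
    expect_lte(abs(sm$values[a, k1] - sm$values[a, k1 - 1]), ramp_step1 + 1e-9)
    expect_lte(abs(sm$values[a, k2 + 1] - sm$values[a, k2]), ramp_step2 + 1e-9)
  }
})

test_that("the high-frequency filter spreads and attenuates an impulse", {
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  sm <- hff_smooth(imp, sigma = 1.5)
  expect_lt(sum(sm^2), sum(imp^2)) # energy reduced
  spread <- function(m) {
    w <- m / sum(m)
    ix <- row(m); iy <- col(m)
    mx <- sum(w * ix); my <- sum(w * iy)
    sum(w * ((ix - mx)^2 + (iy - my)^2))
  }
  expect_gt(spread(sm), spread(imp)) # point spread widened
})

test_that("reconstructing a zero difference yields a zero artifact image", {
  g <- scan_geometry(c(32, 32), n_angles = 16)
  z <- sinogram(matrix(0, 16, g$n_bins), g)
  expect_equal(reconstruct_artifact(z, g)$values, matrix(0, 32, 32))
})

test_that("correction is the identity when the template equals the input", {
  pair <- fx_pair3()
  g <- fx_geometry()
  tmpl <- slice_image(pair$kv$values, pair$kv$pixel_spacing, "template")
  out <- correct_once(pair$kv, tmpl, fx_metal(), g, mar_config(),
                      trace = fx_trace())
  expect_equal(out$values, pair$kv$values, tolerance = 1e-10)
})

test_that("correction is the exact identity for an empty metal mask", {
  pair <- fx_pair3()
  g <- fx_geometry()
  empty <- metal_mask(matrix(FALSE, FX_SIZE, FX_SIZE))
  tmpl <- build_template(pair$kv, fx_masks())
  out <- correct_once(pair$kv, tmpl, empty, g, mar_config())
  expect_identical(out$values, pair$kv$values)
  res <- iterate_mar(pair$kv, pair$mv, g, mar_config(), metal = empty)
  expect_identical(res$corrected$values, pair$kv$values)
})

test_that("one correction pass reduces the inter-metal reconstruction error", {
  pair <- fx_pair3()
  rois <- fx_rois()
  res <- fx_mar()
  corr1 <- pair$kv$values - res$artifacts[[1]]$values
  corr1[fx_metal()$mask] <- pair$kv$values[fx_metal()$mask]
  corr1 <- slice_image(corr1, pair$kv$pixel_spacing)
  expect_lt(nrmsd(corr1, pair$ground_truth_kv, rois$inter_metal),
            nrmsd(pair$kv, pair$ground_truth_kv, rois$inter_metal))
})

test_that("the iteration-1 artifact image tracks the true artifact field", {
  pair <- fx_pair3()
  res <- fx_mar()
  err <- pair$kv$values - pair$ground_truth_kv$values
  nm <- !fx_metal()$mask
  expect_gte(cor(res$artifacts[[1]]$values[nm], err[nm]), 0.2)
})

test_that("each iteration corrects the original kV image, not its own output", {
  pair <- fx_pair3()
  res <- fx_mar()
  for (i in seq_along(res$artifacts)) {
    rebuilt <- pair$kv$values - res$artifacts[[i]]$values
    rebuilt[res$metal$mask] <- pair$kv$values[res$metal$mask]
    if (i == length(res$artifacts)) {
      expect_equal(rebuilt, res$corrected$values)
    }
    # metal pixels always restored from the kV input
    expect_identical(res$corrected$values[res$metal$mask],
                     pair$kv$values[res$metal$mask])
  }
})

test_that("repeated runs of the correction are bit-identical", {
  pair <- fx_pair3()
  g <- fx_geometry()
  a <- iterate_mar(pair$kv, pair$mv, g, mar_config(iterations = 2),
                   masks = fx_masks(), metal = fx_metal())
  b <- iterate_mar(pair$kv, pair$mv, g, mar_config(iterations = 2),
                   masks = fx_masks(), metal = fx_metal())
  expect_identical(a$corrected$values, b$corrected$values)
})

test_that("configuration is validated", {
  expect_error(mar_config(iterations = 0), class = "mvmar_validation_error")
  expect_error(mar_config(delta_n1 = 0), class = "mvmar_validation_error")
  pair <- fx_pair3()
  expect_error(iterate_mar(pair$kv, slice_image(matrix(0, 4, 4)), fx_geometry()),
               class = "mvmar_geometry_error")
})
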