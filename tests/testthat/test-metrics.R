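test_that("ROI mean and noise follow the population definitions", {
  img <- slice_image(matrix(7, 16, 16))
  roi <- roi_circle(c(8, 8), 4)
  expect_equal(roi_mean_and_noise(img, roi), c(mean = 7, sd = 0))
  # two-value ROI: mean 2, population SD 1
  v <- matrix(0, 8, 8); v[4, 4] <- 1; v[4, 5] <- 3; v[5, 4] <- 1; v[5, 5] <- 3
  img2 <- slice_image(v)
  roi2 <- roi_rect(c(4.5, 4.5), c(2, 2))
  expect_equal(roi_mean_and_noise(img2, roi2), c(mean = 2, sd = 1))
})

test_that("ROI statistics match an independent two-pass computation", {
  set.seed(19)
  img <- slice_image(matrix(rnorm(32 * 32, 50, 20), 32, 32))
  roi <- roi_circle(c(16, 16), 4)
  got <- roi_mean_and_noise(img, roi)
  vals <- img$values[roi_mask(roi, c(32, 32))]
  m <- 0; for (v in vals) m <- m + v; m <- m / length(vals)
  s <- 0; for (v in vals) s <- s + (v - m)^2
  expect_equal(got, c(mean = m, sd = sqrt(s / length(vals))))
})

test_that("ROIs are validated against the image", {
  img <- slice_image(matrix(0, 16, 16))
  expect_error(roi_mean_and_noise(img, roi_circle(c(2, 2), 5)),
               class = "mvmar_validation_error")
  expect_error(roi_mean_and_noise(img, roi_circle(c(8, 8), 0.5)),
               class = "mvmar_validation_error")
})

test_that("relative error of ROI means reproduces the published worked examples", {
  expect_equal(round(mre(49.6, 48.0), 2), 0.03)
  expect_equal(round(mre(12.9, 48.0), 2), 0.73)
  expect_equal(mre(5, 5), 0)
  expect_equal(mre(-3, -3), 0)
  expect_error(mre(1, 0), class = "mvmar_undefined_metric")
})

test_that("NRMSD obeys its closed-form special cases", {
  set.seed(23)
  ref <- slice_image(matrix(rnorm(100, 10, 3), 10, 10))
  expect_equal(nrmsd(ref, ref), 0)
  twice <- slice_image(2 * ref$values)
  expect_equal(nrmsd(twice, ref), 1) # numerator equals the reference energy
  zero <- slice_image(matrix(0, 10, 10))
  expect_error(nrmsd(ref, zero), class = "mvmar_undefined_metric")
})

test_that("NRMSD and MAD match brute-force loops on random ROIs", {
  set.seed(29)
  cor_img <- slice_image(matrix(rnorm(400, 30, 15), 20, 20))
  ref_img <- slice_image(matrix(rnorm(400, 28, 14), 20, 20))
  roi <- roi_rect(c(10, 11), c(7, 9))
  m <- roi_mask(roi, c(20, 20))
  num <- 0; den <- 0; sad <- 0; n <- 0
  for (i in 1:20) for (j in 1:20) {
    if (m[i, j]) {
      d <- cor_img$values[i, j] - ref_img$values[i, j]
      num <- num + d^2
      den <- den + ref_img$values[i, j]^2
      sad <- sad + abs(d)
      n <- n + 1
    }
  }
  expect_equal(nrmsd(cor_img, ref_img, roi), sqrt(num / den))
  expect_equal(mad_roi(cor_img, ref_img, roi), sad / n)
})

test_that("offset images have MAD equal to the offset", {
  ref <- slice_image(matrix(seq_len(64), 8, 8))
  shifted <- slice_image(ref$values + 5)
  roi <- roi_circle(c(4, 4), 2)
  expect_equal(mad_roi(shifted, ref, roi), 5)
  expect_equal(mad_roi(ref, ref, roi), 0)
  # NRMSD of the offset image against brute force
  m <- roi_mask(roi, c(8, 8))
  expect_equal(nrmsd(shifted, ref, roi),
               sqrt(sum(m) * 25 / sum(ref$values[m]^2)))
})

test_that("metrics are invariant to ROI pixel enumeration order", {
  set.seed(37)
  a <- slice_image(matrix(rnorm(64), 8, 8))
  b <- slice_image(matrix(rnorm(64), 8, 8))
  roi <- roi_rect(c(4.5, 4.5), c(4, 4))
  at <- slice_image(t(a$values)); bt <- slice_image(t(b$values))
  expect_equal(nrmsd(a, b, roi), nrmsd(at, bt, roi))
  expect_equal(mad_roi(a, b, roi), mad_roi(at, bt, roi))
})

test_that("a self-comparison report is all zeros with the reference noise", {
  ref <- fx_pair0()$kv
  rois <- fx_rois()["soft"]
  rep <- benchmark_report(list(self = ref), ref, rois)
  expect_equal(rep$mre, 0)
  expect_equal(rep$nrmsd, 0)
  expect_equal(rep$mad, 0)
  expect_equal(rep$noise_hu, rep$ref_noise_hu)
})

test_that("reports round-trip through CSV and JSON", {
  ref <- fx_pair0()$kv
  rep <- benchmark_report(list(original = fx_pair3()$kv, self = ref), ref,
                          fx_rois()[c("soft", "inter_metal")])
  csv <- tempfile(fileext = ".csv")
  write_report(rep, csv)
  back <- read_report(csv)
  expect_equal(as.data.frame(back), utils::read.csv(csv), ignore_attr = TRUE)
  # re-serializing the parsed report reproduces the file byte for byte
  csv2 <- tempfile(fileext = ".csv")
  write_report(back, csv2)
  expect_identical(readLines(csv), readLines(csv2))
  js <- tempfile(fileext = ".json")
  write_report(rep, js)
  backj <- read_report(js)
  expect_equal(backj$nrmsd, rep$nrmsd, tolerance = 1e-9)
})
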