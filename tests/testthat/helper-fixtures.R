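# Shared simulation fixtures, built once per test run and memoised so the
# heavier scan-pair simulations are not repeated across test files.  All
# fixtures use the benchmark study conditions: 128x128 grid, 2 mm pixels
# (256 mm field of view), 128 angles, seed 1.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

FX_SIZE <- 128L
FX_PS <- 2

fx_geometry <- function() fx("geometry", function() {
  scan_geometry(c(FX_SIZE, FX_SIZE), n_angles = FX_SIZE, pixel_spacing = FX_PS)
})

fx_rois <- function() dental_rois(c(FX_SIZE, FX_SIZE), FX_PS)

fx_dental_spec <- function(n_inserts = 3, ...) {
  dental_phantom(c(FX_SIZE, FX_SIZE), n_inserts = n_inserts, ...)
}

# dental phantom with the metal primitives removed (reference condition)
fx_nometal_spec <- function(base = fx_dental_spec(2)) {
  n_metal <- sum(vapply(base$primitives, function(p) p$material == "amalgam",
                        logical(1)))
  base$primitives <- base$primitives[seq_len(length(base$primitives) - n_metal)]
  base
}

fx_pair3 <- function() fx("pair3", function() {
  simulate_scan_pair(fx_dental_spec(3), geometry = fx_geometry(), seed = 1)
})

fx_pair2 <- function() fx("pair2", function() {
  simulate_scan_pair(fx_dental_spec(2), geometry = fx_geometry(), seed = 1)
})

fx_pair0 <- function() fx("pair0", function() {
  simulate_scan_pair(fx_nometal_spec(), geometry = fx_geometry(), seed = 1)
})

fx_metal <- function() fx("metal", function() segment_metal(fx_pair3()$kv))

fx_trace <- function() fx("trace", function() {
  metal_trace(fx_metal(), fx_geometry())
})

fx_masks <- function() fx("masks", function() {
  blockwise_segment(fx_pair3()$mv, metal_hint = fx_metal())
})

fx_mar <- function() fx("mar", function() {
  iterate_mar(fx_pair3()$kv, fx_pair3()$mv, fx_geometry(), mar_config(),
              ground_truth = fx_pair3()$ground_truth_kv,
              masks = fx_masks(), metal = fx_metal())
})

fx_limar <- function() fx("limar", function() {
  limar(fx_pair3()$kv, fx_metal(), fx_geometry(), trace = fx_trace())
})

fx_nmar <- function() fx("nmar", function() {
  nmar(fx_pair3()$kv, fx_metal(), fx_geometry(), trace = fx_trace())
})

fx_bone_metal_truth <- function() {
  pair <- fx_pair3()
  labs <- attr(pair$labels, "materials")[unclass(pair$labels)]
  pair$metal_truth | labs == "bone"
}

# Independent oracle: exhaustive two-threshold Otsu by direct evaluation of
# the between-class variance for every ordered histogram-bin pair.
oracle_otsu <- function(values, n_bins = 256) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(findInterval(values, edges, rightmost.closed = TRUE), n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  x <- mids[bin]
  mu <- mean(x)
  best <- -Inf; best_pair <- c(NA, NA)
  for (i in 1:(n_bins - 2)) {
    for (j in (i + 1):(n_bins - 1)) {
      c1 <- x[bin <= i]; c2 <- x[bin > i & bin <= j]; c3 <- x[bin > j]
      if (!length(c1) || !length(c2) || !length(c3)) next
      v <- length(c1) * (mean(c1) - mu)^2 + length(c2) * (mean(c2) - mu)^2 +
        length(c3) * (mean(c3) - mu)^2
      if (v > best * (1 + 1e-12)) {
        best <- v; best_pair <- c(edges[i + 1], edges[j + 1])
      }
    }
  }
  best_pair
}

# small analytic disk image for projector tests
disk_image <- function(n, radius_mm, value, pixel_spacing = 1,
                       center_mm = c(0, 0)) {
  xs <- (seq_len(n) - (n + 1) / 2) * pixel_spacing
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- -t(X)
  v <- matrix(0, n, n)
  v[(X - center_mm[1])^2 + (Y - center_mm[2])^2 <= radius_mm^2] <- value
  slice_image(v, pixel_spacing)
}
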