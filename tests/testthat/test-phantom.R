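test_that("phantom generation is deterministic in the seed", {
  a <- generate_phantom(tiny_phantom_spec(seed = 9))
  b <- generate_phantom(tiny_phantom_spec(seed = 9))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$gt$data, b$gt$data)
  expect_identical(a$weak$data, b$weak$data)
  c <- generate_phantom(tiny_phantom_spec(seed = 10))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("straight tubes rasterize as exact digital disks", {
  sp <- phantom_spec(tube_radius_px = 2, centerline_wobble_amp = 0,
                     noise_sigma = 0, seed = 5)
  p <- generate_phantom(sp)
  # brute-force disk count: pixels with center distance <= 2 -> 13 per tube
  per_slice <- apply(p$gt$data, 1, sum)
  expect_true(all(per_slice == 2 * 13))
})

test_that("weak boxes are margin-dilated tight boxes when jitter is zero", {
  sp <- tiny_phantom_spec(centerline_wobble_amp = 0, noise_sigma = 0,
                          bbox_margin_px = 2L, bbox_jitter_px = 0L, seed = 3)
  p <- generate_phantom(sp)
  for (z in c(1L, 8L)) {
    g <- p$gt$data[z, , ]; w <- p$weak$data[z, , ]
    # per connected tube: compare column ranges of each half
    for (side in list(1:16, 17:32)) {
      gs <- g[, side]; ws <- w[, side]
      gr <- range(which(rowSums(gs) > 0)); gc <- range(which(colSums(gs) > 0))
      wr <- range(which(rowSums(ws) > 0)); wc <- range(which(colSums(ws) > 0))
      expect_equal(wr, gr + c(-2, 2))
      expect_equal(wc, gc + c(-2, 2))
    }
  }
})

test_that("ground truth is always contained in the weak mask", {
  set.seed(1)
  samples <- generate_dataset(4, tiny_phantom_spec(), seed = 77)
  for (s in samples) expect_true(all(s$gt$data <= s$weak$data))
})

test_that("per-slice weak-area distribution is right-skewed across a dataset", {
  samples <- generate_dataset(21, phantom_spec(), seed = 7)  # 504 slices
  areas <- unlist(lapply(samples, function(s) apply(s$weak$data, 1, sum)))
  expect_gte(length(areas), 500)
  skew <- mean((areas - mean(areas))^3) / mean((areas - mean(areas))^2)^1.5
  expect_gt(skew, 0)
})

test_that("noise-free tubes are exactly recoverable by thresholding", {
  sp <- tiny_phantom_spec(noise_sigma = 0, seed = 13)
  p <- generate_phantom(sp)
  thr <- (sp$tube_intensity + sp$background_intensity) / 2
  expect_identical(1L * (p$volume$data < thr), 1L * (p$gt$data == 1L))
})

test_that("dataset generation draws per-volume contrast and derived seeds", {
  ds <- generate_dataset(10, tiny_phantom_spec(), c(0.1, 0.4), seed = 5)
  tis <- vapply(ds, function(s) s$spec$tube_intensity, numeric(1))
  seeds <- vapply(ds, function(s) s$spec$seed, integer(1))
  expect_length(unique(seeds), 10)
  expect_true(all(tis >= 0.1 & tis <= 0.4))
  expect_gt(length(unique(tis)), 1)
  # degenerate range: all volumes share the intensity
  dg <- generate_dataset(3, tiny_phantom_spec(), c(0.2, 0.2), seed = 5)
  expect_true(all(vapply(dg, function(s) s$spec$tube_intensity, numeric(1)) == 0.2))
  # reproducible
  ds2 <- generate_dataset(10, tiny_phantom_spec(), c(0.1, 0.4), seed = 5)
  expect_identical(ds[[4]]$volume$data, ds2[[4]]$volume$data)
  expect_error(generate_dataset(0, tiny_phantom_spec()), "n_volumes")
  expect_error(generate_dataset(2, tiny_phantom_spec(), c(0.4, 0.1)), "contrast_range")
})

test_that("tubes leaving the field of view raise a geometry error", {
  expect_error(phantom_spec(shape = c(8L, 20L, 20L), tube_separation_px = 30),
               "field of view")
  expect_error(phantom_spec(tube_intensity = 0.9), "tube < background")
})
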