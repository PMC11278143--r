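make_pairs <- function(n, area_px = 4L, h = 16L, w = 16L) {
  lapply(seq_len(n), function(i) {
    m <- matrix(0L, h, w)
    m[seq_len(min(area_px, h)), 1] <- 1L
    list(image = array(runif(h * w * 3), c(h, w, 3L)), mask = m,
         volume_id = 1L, slice_index = i, provenance = "bbox")
  })
}

test_that("area stratification thresholds at mean plus one population SD", {
  # areas [1,1,1,1,10]: mean 2.8, pop SD 3.6 -> threshold 6.4
  pairs <- c(make_pairs(4, area_px = 1L), make_pairs(1, area_px = 10L))
  strat <- stratify_by_area(pairs)
  expect_equal(strat$threshold, 6.4, tolerance = 1e-12)
  expect_equal(strat$big_ids, 5L)
  expect_equal(strat$small_ids, 1:4)
  # all equal: SD 0, ties go small, big empty
  eq <- stratify_by_area(make_pairs(6, area_px = 3L))
  expect_length(eq$big_ids, 0)
  expect_length(eq$small_ids, 6)
  # single item is small
  one <- stratify_by_area(make_pairs(1))
  expect_equal(one$small_ids, 1L)
  expect_error(stratify_by_area(list()), "empty")
})

test_that("augment_subset hits exact target counts including fractional multipliers", {
  pairs <- make_pairs(10)
  pol <- augmentation_policy()
  expect_length(augment_subset(pairs, pol, 7, seed = 1), 70)
  expect_length(augment_subset(pairs, pol, 1.3, seed = 1), 13)
  ident <- augment_subset(pairs, pol, 1, seed = 1)
  expect_identical(ident, pairs)
  expect_error(augment_subset(pairs, pol, 0.5), "multiplier")
})

test_that("augmented dataset counts follow the stratified multipliers", {
  pairs <- c(make_pairs(100, area_px = 2L), make_pairs(10, area_px = 14L))
  strat <- stratify_by_area(pairs)
  expect_length(strat$small_ids, 100)
  expect_length(strat$big_ids, 10)
  out <- augment_dataset(pairs, strat, augmentation_policy(), seed = 2)
  expect_length(out, 200)  # 130 small + 70 big
  expect_true(all(vapply(out, function(p) all(p$mask %in% c(0, 1)), logical(1))))
  # empty big stratum: output is 1.3x small only
  small_only <- make_pairs(10, area_px = 3L)
  out2 <- augment_dataset(small_only, stratify_by_area(small_only),
                          augmentation_policy(), seed = 3)
  expect_length(out2, 13)
})

test_that("augmentation is deterministic under a fixed seed", {
  pairs <- make_pairs(8, area_px = 5L)
  pol <- augmentation_policy()
  a <- augment_dataset(pairs, stratify_by_area(pairs), pol, seed = 11)
  b <- augment_dataset(pairs, stratify_by_area(pairs), pol, seed = 11)
  expect_identical(a, b)
})

test_that("geometric transforms keep masks binary and flips invert exactly", {
  set.seed(4)
  pairs <- make_pairs(1, area_px = 6L)
  rot_pol <- augmentation_policy(rotation_p = 1, hflip_p = 0, vflip_p = 0,
                                 contrast_p = 0, gamma_p = 0, blur_p = 0,
                                 noise_p = 0, shift_zoom_p = 1)
  aug <- augment_subset(pairs, rot_pol, 2, seed = 5)[[2]]
  expect_true(all(aug$mask %in% c(0, 1)))
  expect_true(isTRUE(aug$augmented))
  # flip-only: flipping back restores the original exactly
  flip_pol <- augmentation_policy(rotation_p = 0, hflip_p = 1, vflip_p = 0,
                                  contrast_p = 0, gamma_p = 0, blur_p = 0,
                                  noise_p = 0, shift_zoom_p = 0)
  fl <- augment_subset(pairs, flip_pol, 2, seed = 6)[[2]]
  expect_identical(fl$mask[, rev(seq_len(ncol(fl$mask)))], pairs[[1]]$mask)
  expect_equal(fl$image[, rev(seq_len(ncol(fl$mask))), ], pairs[[1]]$image,
               ignore_attr = TRUE)
})

test_that("with all probabilities zero augmentation duplicates originals", {
  pairs <- make_pairs(10, area_px = 4L)
  off <- augmentation_policy(rotation_p = 0, hflip_p = 0, vflip_p = 0,
                             contrast_p = 0, gamma_p = 0, blur_p = 0,
                             noise_p = 0, shift_zoom_p = 0)
  out <- augment_subset(pairs, off, 1.3, seed = 7)
  expect_length(out, 13)
  for (j in 1:3) {
    expect_equal(out[[10 + j]]$image, pairs[[j]]$image)
    expect_identical(out[[10 + j]]$mask, pairs[[j]]$mask)
  }
})
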