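test_that("erosion with the radius-1 disk matches the brute-force oracle", {
  # solid 3x3 block -> only the center survives
  m <- matrix(0L, 7, 7); m[3:5, 3:5] <- 1L
  e <- erode_disk1(m)
  expect_equal(sum(e), 1)
  expect_equal(e[4, 4], 1L)
  # isolated pixel vanishes
  s <- matrix(0L, 5, 5); s[3, 3] <- 1L
  expect_true(all(erode_disk1(s) == 0))
  # all ones: border eroded (outside image is background)
  a <- matrix(1L, 6, 8)
  ea <- erode_disk1(a)
  expect_true(all(ea[2:5, 2:7] == 1))
  expect_true(all(ea[c(1, 6), ] == 0) && all(ea[, c(1, 8)] == 0))
  # random masks vs pixel-loop oracle
  set.seed(8)
  for (k in 1:30) {
    r <- rand_mask(sample(4:12, 1), sample(4:12, 1), 0.6)
    expect_identical(erode_disk1(r), naive_erode(r))
  }
})

test_that("side split is a partition at the vertical midline", {
  m <- matrix(runif(240 * 240) > 0.5, 240, 240) * 1L
  sp <- split_sides(m)
  expect_equal(ncol(sp$left), 120)
  expect_equal(ncol(sp$right), 120)
  expect_identical(cbind(sp$left, sp$right), m)
  left_only <- matrix(0L, 6, 8); left_only[2, 1:3] <- 1L
  expect_true(all(split_sides(left_only)$right == 0))
})

test_that("per-side IoU gate accepts at >= 50% and reverts below", {
  H <- 6L; W <- 8L
  bbox <- matrix(0L, H, W)
  bbox[2:3, 1:2] <- 1L   # left box, 4 px
  bbox[2:3, 6:7] <- 1L   # right box, 4 px
  pred <- matrix(0L, H, W)
  pred[2:3, 1] <- 1L; pred[2, 2] <- 1L   # 3 of 4 left px -> IoU 0.75
  pred[2, 6] <- 1L                        # 1 of 4 right px -> IoU 0.25
  ar <- accept_or_revert(pred, bbox, 0.5)
  expect_true(ar$side_accept[["left"]])
  expect_false(ar$side_accept[["right"]])
  expect_equal(unname(ar$side_iou), c(0.75, 0.25))
  expect_identical(ar$mask[, 1:4], pred[, 1:4])     # accepted side kept
  expect_identical(ar$mask[, 5:8], bbox[, 5:8])     # reverted side restored
  # identity: prediction equal to the boxes is accepted everywhere
  id <- accept_or_revert(bbox, bbox, 0.5)
  expect_true(all(id$side_accept))
  expect_identical(id$mask, bbox)
  # empty-empty side counts as accepted
  empty_right <- matrix(0L, H, W); empty_right[2:3, 1:2] <- 1L
  er <- accept_or_revert(empty_right, empty_right, 0.5)
  expect_true(all(er$side_accept))
})

test_that("clipping is an elementwise AND with the boxes", {
  bbox <- matrix(0L, 5, 6); bbox[2:4, 2:3] <- 1L
  m <- matrix(1L, 5, 6)
  expect_identical(clip_to_bbox(m, bbox), bbox)
  inside <- matrix(0L, 5, 6); inside[3, 2] <- 1L
  expect_identical(clip_to_bbox(inside, bbox), inside)
  expect_true(all(clip_to_bbox(m, matrix(0L, 5, 6)) == 0))
})

test_that("update_masks equals the brute-force composition on random fixtures", {
  set.seed(9)
  cfg <- selftrain_config()
  for (k in 1:50) {
    h <- sample(6:16, 1); w <- sample(c(6, 8, 10, 12, 14, 16), 1)
    pred <- rand_mask(h, w, 0.5)
    bbox <- rand_mask(h, w, 0.6)
    round_idx <- sample(0:6, 1)
    pairs <- mask_fixture_pairs(list(bbox))
    rec <- update_masks(NULL, pairs, list(bbox), round_idx, cfg,
                        predictions = list(pred))[[1]]
    oracle <- naive_update(pred, bbox, round_idx, cfg$erosion_rounds, cfg$iou_accept)
    expect_identical(rec$mask, oracle)
    expect_true(all(rec$mask <= bbox))  # containment
    expect_equal(rec$round, round_idx)
  }
})

test_that("erosion applies in rounds 0-3 only", {
  solid <- matrix(1L, 10, 10)
  pairs <- mask_fixture_pairs(list(solid))
  for (r in 0:6) {
    rec <- update_masks(NULL, pairs, list(solid), r, selftrain_config(),
                        predictions = list(solid))[[1]]
    if (r < 4) {
      expect_equal(sum(rec$mask), 8 * 8)  # border eroded
    } else {
      expect_equal(sum(rec$mask), 100)    # untouched
    }
  }
})

test_that("an all-background ensemble reverts every mask to its bounding box", {
  set.seed(12)
  bboxes <- replicate(10, {
    b <- matrix(0L, 12, 12)
    b[3:6, 2:4] <- 1L; b[4:8, 8:10] <- 1L
    b
  }, simplify = FALSE)
  pairs <- mask_fixture_pairs(bboxes)
  zeros <- lapply(bboxes, function(b) matrix(0L, 12, 12))
  recs <- update_masks(NULL, pairs, bboxes, 0, selftrain_config(),
                       predictions = zeros)
  for (i in seq_along(recs)) expect_identical(recs[[i]]$mask, bboxes[[i]])
})

test_that("ensemble averaging binarizes the mean probability at 0.5 inclusive", {
  # arithmetic on hand-picked per-pixel probability tuples
  expect_identical(binarize(mean(c(0.4, 0.4, 0.4, 0.9, 0.9))), 1L)  # mean 0.6
  expect_identical(binarize(mean(c(0.4, 0.4, 0.4, 0.4, 0.9))), 1L)  # mean 0.5 exactly
  expect_identical(binarize(mean(c(0.4, 0.4, 0.4, 0.4, 0.4))), 0L)
  # five identical nets act like one
  net <- build_model(tiny_model_cfg(), seed = 6)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  single <- binarize(predict_proba(net, x), 0.5)
  ens <- ensemble_predict(list(net, net, net, net, net), x)
  expect_identical(ens, single)
  expect_error(ensemble_predict(list(), x), "empty ensemble")
})
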