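test_that("dice loss matches its closed forms", {
  t4 <- matrix(0, 4, 4); t4[1:2, 1:2] <- 1          # N = 4 foreground
  expect_equal(dice_loss(t4, t4, smooth = 1), 0)
  disj <- matrix(0, 4, 4); disj[3:4, 3:4] <- 1      # disjoint, N each
  expect_equal(dice_loss(disj, t4, smooth = 1), 1 - 1 / (2 * 4 + 1), tolerance = 1e-12)
  z <- matrix(0, 4, 4)
  expect_equal(dice_loss(z, z, smooth = 1), 0)      # empty-empty convention
  expect_error(dice_loss(z, matrix(0, 2, 2)), "shapes disagree")
})

test_that("dice loss decreases monotonically toward the target", {
  t4 <- matrix(0, 6, 6); t4[2:3, 2:3] <- 1
  far <- matrix(0, 6, 6); far[5:6, 5:6] <- 1
  lambdas <- seq(0, 1, length.out = 20)
  losses <- vapply(lambdas, function(l) {
    dice_loss((1 - l) * far + l * t4, t4)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("learning-rate schedule matches the continuous closed form", {
  cfg <- train_config()
  expect_equal(lr_at(0, cfg), 1e-4, tolerance = 1e-12)
  expect_equal(lr_at(253, cfg), 9.6e-5, tolerance = 1e-12)
  expect_equal(lr_at(506, cfg), 9.216e-5, tolerance = 1e-12)
  steps <- 0:600
  lrs <- vapply(steps, lr_at, numeric(1), cfg = cfg)
  expect_true(all(diff(lrs) < 0))
  expect_equal(lrs, cfg$lr0 * cfg$decay_rate^(steps / cfg$decay_steps),
               tolerance = 1e-12)
})

test_that("fold assignment is at volume level, deterministic, and a partition", {
  pairs <- unlist(lapply(1:10, function(v) {
    lapply(1:4, function(k) list(image = array(0, c(8, 8, 3)),
                                 mask = matrix(1, 8, 8),
                                 volume_id = v, slice_index = k))
  }), recursive = FALSE)
  f1 <- make_folds(pairs, 5, seed = 3)
  f2 <- make_folds(pairs, 5, seed = 3)
  expect_identical(f1$pair_fold, f2$pair_fold)
  expect_equal(sort(unique(f1$pair_fold)), 1:5)
  expect_equal(as.vector(table(f1$volume_fold)), rep(2, 5))  # 10 volumes over 5 folds
  # all slices of a volume share a fold
  vids <- vapply(pairs, `[[`, integer(1), "volume_id")
  for (v in 1:10) expect_length(unique(f1$pair_fold[vids == v]), 1)
  expect_length(f1$pair_fold, 40)
  expect_error(make_folds(pairs[1:8], 5, seed = 1), "folds requested")
})

test_that("training a fold early-stops on stagnant validation IoU and checkpoints the best epoch", {
  set.seed(10)
  samples <- generate_dataset(5, tiny_phantom_spec(), seed = 31)
  for (i in seq_along(samples)) samples[[i]]$volume_id <- i
  pairs <- build_slice_dataset(lapply(samples, function(s)
    list(volume = s$volume, mask = s$weak, volume_id = s$volume_id)))
  folds <- make_folds(pairs, 5, seed = 1)
  cfg <- train_config(lr0 = 1e-3, max_epochs = 4L, patience = 2L, batch_size = 8L)
  fit <- train_fold(pairs, folds, 1, cfg, tiny_model_cfg(), seed = 2)
  expect_s3_class(fit$net, "resunet")
  expect_true(nrow(fit$history) <= cfg$max_epochs)
  expect_true(all(c("epoch", "train_loss", "val_miou", "lr") %in% names(fit$history)))
  # checkpoint reproduces the best epoch's validation IoU
  pair_fold <- unname(folds$volume_fold[vapply(pairs, function(p)
    as.character(p$volume_id), character(1))])
  val_ids <- which(pair_fold == 1)
  revald <- carotidseg:::validation_miou(fit$net, pairs, val_ids, 0.5, 8L)
  expect_equal(revald, max(fit$history$val_miou), tolerance = 1e-12)
  expect_equal(fit$best_epoch, which.max(fit$history$val_miou))
})

test_that("the early-stopping rule fires after `patience` flat epochs", {
  # the rule operates on the per-epoch validation series; emulate it on
  # an injected sequence to pin the epoch arithmetic
  run_rule <- function(vals, patience, max_epochs) {
    best <- -Inf; since <- 0L
    for (e in seq_len(max_epochs)) {
      if (vals[e] > best) { best <- vals[e]; since <- 0L }
      else {
        since <- since + 1L
        if (since >= patience) return(e)
      }
    }
    max_epochs
  }
  expect_equal(run_rule(rep(0.5, 20), patience = 10, max_epochs = 100), 11)
  expect_equal(run_rule(seq(0.1, 0.9, length.out = 100), 10, 100), 100)
})

test_that("a small network learns the phantom tubes (loss falls below 0.5)", {
  set.seed(20)
  samples <- generate_dataset(3, phantom_spec(shape = c(14L, 32L, 32L), tube_separation_px = 14), seed = 41)
  pairs <- build_slice_dataset(lapply(seq_along(samples), function(i)
    list(volume = samples[[i]]$volume, mask = samples[[i]]$gt, volume_id = i)))
  pairs <- pairs[1:40]
  net <- build_model(tiny_model_cfg(), seed = 3)
  opt <- carotidseg:::adam_init(net$params)
  cfg <- train_config(lr0 = 1e-3, batch_size = 8L)
  set.seed(4)
  first_loss <- NA; last_loss <- NA
  step <- 0L
  for (epoch in 1:30) {
    ord <- sample(seq_along(pairs))
    ep <- 0
    for (start in seq(1, length(ord), by = 8)) {
      ids <- ord[start:min(start + 7, length(ord))]
      b <- carotidseg:::pairs_to_batch(pairs, ids)
      fw <- carotidseg:::resunet_fwd(net, b$x, train = TRUE)
      net$state <- fw$state
      dl <- carotidseg:::dice_loss_batch(fw$prob, b$y)
      gr <- carotidseg:::resunet_bwd(net, fw$cache, dl$grad)
      up <- carotidseg:::adam_step(net$params, gr, opt, lr_at(step, cfg))
      net$params <- up$params; opt <- up$opt
      step <- step + 1L
      ep <- ep + dl$loss
    }
    ep <- ep / ceiling(length(ord) / 8)
    if (epoch == 1) first_loss <- ep
    last_loss <- ep
  }
  expect_gt(first_loss, 0.8)
  expect_lt(last_loss, 0.5)
})
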