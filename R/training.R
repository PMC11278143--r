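#' Training configuration
#'
#' Reference defaults: Adam with an initial learning rate of 0.0001
#' under continuous exponential decay (rate 0.96 every 253 steps),
#' Dice loss with smoothing 1, at most 100 epochs with early stopping
#' after 10 epochs without validation mean-IoU improvement, 5-fold
#' cross-validation at volume level.
#'
#' @param lr0 initial learning rate.
#' @param decay_steps steps per decay period.
#' @param decay_rate multiplicative decay per period.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience in epochs.
#' @param n_folds number of cross-validation folds.
#' @param dice_smooth Dice-loss smoothing constant.
#' @param batch_size minibatch size.
#' @param seed master seed for fold training.
#' @return a `train_config` list.
#' @export
train_config <- function(lr0 = 1e-4, decay_steps = 253L, decay_rate = 0.96,
                         max_epochs = 100L, patience = 10L, n_folds = 5L,
                         dice_smooth = 1.0, batch_size = 8L, seed = 1L) {
  cfg <- list(lr0 = lr0, decay_steps = as.integer(decay_steps),
              decay_rate = decay_rate, max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), n_folds = as.integer(n_folds),
              dice_smooth = dice_smooth, batch_size = as.integer(batch_size),
              seed = as.integer(seed))
  if (cfg$lr0 <= 0) stopf("train_config: lr0 must be > 0")
  if (cfg$decay_rate <= 0 || cfg$decay_rate > 1) stopf("train_config: decay_rate must be in (0, 1]")
  if (cfg$patience > cfg$max_epochs) stopf("train_config: patience must be <= max_epochs")
  class(cfg) <- "train_config"
  cfg
}

#' Soft Dice loss
#'
#' `1 - (2 sum(pred * target) + smooth) / (sum(pred) + sum(target) + smooth)`.
#' Zero for a perfect binary match; the smoothing constant makes the
#' empty-prediction/empty-target case well defined (loss 0).
#'
#' @param pred probability array.
#' @param target binary array of the same shape.
#' @param smooth smoothing constant (default 1).
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, smooth = 1.0) {
  check_same_shape(pred, target)
  num <- 2 * sum(pred * target) + smooth
  den <- sum(pred) + sum(target) + smooth
  1 - num / den
}

# Per-sample soft Dice over a batch (H, W, 1, N) vs (H, W, 1, N),
# returning mean loss and d(loss)/d(pred).
dice_loss_batch <- function(pred, target, smooth = 1.0) {
  N <- dim(pred)[4]
  gp <- array(0, dim(pred))
  loss <- 0
  for (n in seq_len(N)) {
    p <- pred[, , , n]; t <- target[, , , n]
    num <- 2 * sum(p * t) + smooth
    den <- sum(p) + sum(t) + smooth
    loss <- loss + (1 - num / den)
    gp[, , , n] <- -(2 * t * den - num) / den^2 / N
  }
  list(loss = loss / N, grad = gp)
}

#' Learning rate at a given optimizer step
#'
#' Continuous (non-staircase) exponential decay:
#' `lr0 * decay_rate^(step / decay_steps)`.
#'
#' @param step optimizer step, `>= 0`.
#' @param cfg a [train_config()].
#' @return the learning rate.
#' @export
lr_at <- function(step, cfg) {
  cfg$lr0 * cfg$decay_rate^(step / cfg$decay_steps)
}

#' Assign slice pairs to cross-validation folds at volume level
#'
#' Volumes are shuffled with `seed` and dealt round-robin into
#' `n_folds` folds; every slice of a volume shares its fold, so no
#' volume leaks between a training and validation split. The split is
#' computed once and reused identically across all self-training
#' rounds.
#'
#' @param pairs list of `slice_pair`s.
#' @param n_folds number of folds.
#' @param seed shuffle seed.
#' @return a `fold_split`: list with `volume_fold` (named vector) and
#'   `pair_fold` (integer vector over `pairs`, folds `1..n_folds`).
#' @export
make_folds <- function(pairs, n_folds = 5L, seed = 1L) {
  vids <- vapply(pairs, function(p) as.character(p$volume_id), character(1))
  vols <- unique(vids)
  if (length(vols) < n_folds) {
    stopf("make_folds: %d volumes but %d folds requested", length(vols), n_folds)
  }
  set.seed(seed)
  vols <- sample(vols)
  vf <- setNames(rep(seq_len(n_folds), length.out = length(vols)), vols)
  structure(list(volume_fold = vf, pair_fold = unname(vf[vids]),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "fold_split")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

pairs_to_batch <- function(pairs, ids) {
  H <- dim(pairs[[ids[1]]]$image)[1]; W <- dim(pairs[[ids[1]]]$image)[2]
  x <- array(0, c(H, W, 3L, length(ids)))
  y <- array(0, c(H, W, 1L, length(ids)))
  for (j in seq_along(ids)) {
    x[, , , j] <- pairs[[ids[j]]]$image
    y[, , 1, j] <- pairs[[ids[j]]]$mask
  }
  list(x = x, y = y)
}

validation_miou <- function(net, pairs, ids, threshold = 0.5, batch_size = 8L) {
  if (length(ids) == 0) return(NA_real_)
  vals <- numeric(0)
  for (start in seq(1, length(ids), by = batch_size)) {
    chunk <- ids[start:min(start + batch_size - 1L, length(ids))]
    b <- pairs_to_batch(pairs, chunk)
    p <- resunet_fwd(net, b$x, train = FALSE)$prob
    for (j in seq_along(chunk)) {
      vals <- c(vals, iou(binarize(p[, , 1, j], threshold), b$y[, , 1, j]))
    }
  }
  mean(vals)
}

#' Train one cross-validation fold
#'
#' Trains on every fold but `fold`, validating on `fold` after each
#' epoch with mean IoU at threshold 0.5. Stops when validation mean
#' IoU has not improved for `cfg$patience` epochs or at
#' `cfg$max_epochs`, and returns the weights of the best validation
#' epoch.
#'
#' @param pairs training `slice_pair`s (possibly augmented); augmented
#'   copies are excluded from validation.
#' @param folds a [make_folds()] split aligned with `pairs` via each
#'   pair's `volume_id`.
#' @param fold validation fold in `1..n_folds`.
#' @param cfg a [train_config()].
#' @param model_cfg a [resunet_config()].
#' @param seed weight-init / shuffling seed.
#' @param verbose print per-epoch progress.
#' @return list with `net` (best weights), `history` (data.frame of
#'   epoch, train_loss, val_miou, lr), `best_epoch`, `fold`.
#' @export
train_fold <- function(pairs, folds, fold, cfg, model_cfg, seed = 1L,
                       verbose = FALSE) {
  pair_fold <- unname(folds$volume_fold[vapply(pairs, function(p)
    as.character(p$volume_id), character(1))])
  train_ids <- which(pair_fold != fold)
  val_ids <- which(pair_fold == fold &
                     !vapply(pairs, function(p) isTRUE(p$augmented), logical(1)))
  if (length(train_ids) == 0) stopf("train_fold: empty training split for fold %d", fold)
  net <- build_model(model_cfg, seed = seed)
  opt <- adam_init(net$params)
  set.seed(derive_seed(seed, 7L))
  step <- 0L
  best <- -Inf; best_params <- net$params; best_state <- net$state
  best_epoch <- 0L; since_best <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_miou = numeric(), lr = numeric())
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(train_ids)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      ids <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      b <- pairs_to_batch(pairs, ids)
      fw <- resunet_fwd(net, b$x, train = TRUE)
      net$state <- fw$state
      dl <- dice_loss_batch(fw$prob, b$y, cfg$dice_smooth)
      grads <- resunet_bwd(net, fw$cache, dl$grad)
      upd <- adam_step(net$params, grads, opt, lr_at(step, cfg))
      net$params <- upd$params; opt <- upd$opt
      step <- step + 1L
      ep_loss <- ep_loss + dl$loss; nb <- nb + 1L
    }
    vm <- validation_miou(net, pairs, val_ids, model_cfg$prob_threshold,
                          cfg$batch_size)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                         val_miou = vm, lr = lr_at(step - 1L, cfg)))
    if (verbose) {
      message(sprintf("fold %d epoch %3d loss %.4f val mIoU %.4f",
                      fold, epoch, ep_loss / nb, vm))
    }
    if (!is.na(vm) && vm > best) {
      best <- vm; best_params <- net$params; best_state <- net$state
      best_epoch <- epoch; since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$patience) break
    }
  }
  net$params <- best_params
  net$state <- best_state
  list(net = net, history = history, best_epoch = best_epoch,
       best_val_miou = best, fold = fold)
}

#' Train the full cross-validation ensemble for one round
#'
#' Applies area-stratified augmentation fresh (when a `policy` is
#' given), then trains one network per fold; per-fold seeds derive
#' from `round_seed` so the ensemble is reproducible.
#'
#' @param pairs original (un-augmented) `slice_pair`s carrying the
#'   round's training masks.
#' @param folds the persistent [make_folds()] split.
#' @param cfg a [train_config()].
#' @param model_cfg a [resunet_config()].
#' @param policy optional [augmentation_policy()].
#' @param round_seed seed for augmentation and fold training.
#' @param verbose print progress.
#' @return list of `cfg$n_folds` [train_fold()] results.
#' @export
train_round <- function(pairs, folds, cfg, model_cfg, policy = NULL,
                        round_seed = 1L, verbose = FALSE) {
  data <- pairs
  if (!is.null(policy)) {
    strat <- stratify_by_area(pairs)
    data <- augment_dataset(pairs, strat, policy,
                            seed = derive_seed(round_seed, 11L))
  }
  lapply(seq_len(cfg$n_folds), function(f) {
    train_fold(data, folds, f, cfg, model_cfg,
               seed = derive_seed(round_seed, 23L, f), verbose = verbose)
  })
}

#' Write per-fold training history to CSV
#' @param fit a [train_fold()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(fit, path) {
  write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
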