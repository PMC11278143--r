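#' Self-training configuration
#'
#' The recursive mask-update scheme: seven rounds (indexed 0..6), each
#' training a 5-fold ensemble on the current masks and then refining
#' them by ensemble prediction, morphological erosion with a radius-1
#' disk (the 4-connected cross) during the first `erosion_rounds`
#' rounds only, a per-carotid IoU acceptance gate at `iou_accept`
#' against the original bounding boxes, and clipping to the boxes.
#'
#' @param n_rounds number of rounds (default 7, rounds 0..6).
#' @param erosion_rounds rounds that apply erosion (default 4, i.e.
#'   rounds 0-3).
#' @param iou_accept per-side IoU acceptance threshold (default 0.5,
#'   inclusive).
#' @param erosion_conn connectivity of the structuring element: 4 (the
#'   radius-1 digital disk / cross, the default) or 8 (full 3x3 square).
#' @param split_col column at which images are split into a left and a
#'   right carotid side; `NULL` means the vertical midline `W %/% 2`.
#' @return a `selftrain_config` list.
#' @export
selftrain_config <- function(n_rounds = 7L, erosion_rounds = 4L,
                             iou_accept = 0.5, erosion_conn = 4L,
                             split_col = NULL) {
  cfg <- list(n_rounds = as.integer(n_rounds),
              erosion_rounds = as.integer(erosion_rounds),
              iou_accept = iou_accept,
              erosion_conn = as.integer(erosion_conn),
              split_col = if (is.null(split_col)) NULL else as.integer(split_col))
  if (cfg$iou_accept <= 0 || cfg$iou_accept >= 1) {
    stopf("selftrain_config: iou_accept must be in (0, 1)")
  }
  if (cfg$erosion_rounds > cfg$n_rounds) {
    stopf("selftrain_config: erosion_rounds must be <= n_rounds")
  }
  if (!cfg$erosion_conn %in% c(4L, 8L)) {
    stopf("selftrain_config: erosion_conn must be 4 or 8")
  }
  class(cfg) <- "selftrain_config"
  cfg
}

#' Ensemble prediction for a batch of pseudo-RGB slices
#'
#' Averages the probability maps of the cross-validation models and
#' binarizes the mean at 0.5 (inclusive).
#'
#' @param nets non-empty list of `resunet`s (or [train_fold()] results).
#' @param batch one `H x W x 3` slice, a list of slices, or an
#'   `(H, W, 3, N)` array.
#' @param threshold binarization threshold (default 0.5).
#' @return binary mask(s): `H x W` matrix for a single slice, else an
#'   `(H, W, N)` array.
#' @export
ensemble_predict <- function(nets, batch, threshold = 0.5) {
  if (length(nets) == 0) stopf("ensemble_predict: empty ensemble")
  nets <- lapply(nets, function(n) if (inherits(n, "resunet")) n else n$net)
  probs <- lapply(nets, function(n) predict_proba(n, batch))
  binarize(Reduce(`+`, probs) / length(probs), threshold)
}

#' Morphological erosion with the radius-1 digital disk
#'
#' A pixel survives iff it and its four axial neighbours are all
#' foreground; pixels outside the image count as background, so the
#' one-pixel border of an all-ones image is always eroded away. With
#' `conn = 8` the full 3x3 square is used instead.
#'
#' @param mask binary matrix.
#' @param conn 4 (cross, default) or 8 (square).
#' @return eroded binary (integer) matrix.
#' @export
erode_disk1 <- function(mask, conn = 4L) {
  m <- mask != 0
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- m
  keep <- pad[2:(H + 1), 2:(W + 1)] &
    pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  if (conn == 8L) {
    keep <- keep & pad[1:H, 1:W] & pad[1:H, 3:(W + 2)] &
      pad[3:(H + 2), 1:W] & pad[3:(H + 2), 3:(W + 2)]
  }
  matrix(as.integer(keep), H, W)
}

#' Split a mask into left and right carotid sides
#'
#' Fixed vertical split: left = columns `1..split_col`, right = the
#' rest. Concatenating the halves reproduces the input.
#'
#' @param mask binary matrix.
#' @param split_col last column of the left half; defaults to `W %/% 2`.
#' @return list with `left` and `right` matrices.
#' @export
split_sides <- function(mask, split_col = NULL) {
  W <- ncol(mask)
  sc <- split_col %||% (W %/% 2L)
  list(left = mask[, seq_len(sc), drop = FALSE],
       right = mask[, (sc + 1L):W, drop = FALSE])
}

#' Per-carotid IoU gate: accept a refined side or revert to its box
#'
#' For each side independently, the prediction is kept if its IoU with
#' that side of the bounding-box mask is `>= iou_accept`; otherwise the
#' side reverts to the bounding box. A side empty in both masks counts
#' as accepted (IoU 1), so carotid-free half-images never spuriously
#' revert; a prediction on a side with no box scores IoU 0 and reverts
#' to empty.
#'
#' @param pred binary prediction matrix.
#' @param bbox binary bounding-box matrix of the same shape.
#' @param iou_accept acceptance threshold (default 0.5, inclusive).
#' @param split_col see [split_sides()].
#' @return list with `mask` (the concatenated result), `side_accept`
#'   (logical left/right), `side_iou` (numeric left/right).
#' @export
accept_or_revert <- function(pred, bbox, iou_accept = 0.5, split_col = NULL) {
  check_same_shape(pred, bbox)
  ps <- split_sides(pred, split_col)
  bs <- split_sides(bbox, split_col)
  side_iou <- c(left = iou(ps$left, bs$left, empty = 1),
                right = iou(ps$right, bs$right, empty = 1))
  acc <- side_iou >= iou_accept
  left <- if (acc[1]) ps$left else bs$left
  right <- if (acc[2]) ps$right else bs$right
  list(mask = cbind(left, right), side_accept = acc, side_iou = side_iou)
}

#' Clip a mask to its bounding boxes
#'
#' Elementwise AND: pixels outside the boxes are erased, so every
#' refined mask stays inside its weak label.
#'
#' @param mask,bbox binary matrices of the same shape.
#' @return binary (integer) matrix, a subset of `bbox`.
#' @export
clip_to_bbox <- function(mask, bbox) {
  check_same_shape(mask, bbox)
  matrix(as.integer(mask != 0 & bbox != 0), nrow(mask), ncol(mask))
}

#' Refine the training masks of every slice with the round's ensemble
#'
#' Per slice: ensemble prediction, erosion (only while
#' `round_idx < cfg$erosion_rounds`), the per-carotid accept/revert
#' gate against the original boxes, then clipping to the boxes.
#'
#' @param nets the round's list of trained fold models.
#' @param pairs list of `slice_pair`s (supplies the images).
#' @param bboxes list of binary matrices: the original weak bounding
#'   boxes, aligned with `pairs`.
#' @param round_idx 0-based round index (0..n_rounds-1).
#' @param cfg a [selftrain_config()].
#' @param batch_size inference batch size.
#' @param predictions optional list of precomputed binary prediction
#'   matrices aligned with `pairs`; when given, the ensemble is not
#'   run (useful for reprocessing saved predictions and for testing
#'   the post-processing chain in isolation).
#' @return list of mask records: `list(mask, provenance = "refined",
#'   round, side_accept, side_iou)` per slice.
#' @export
update_masks <- function(nets, pairs, bboxes, round_idx, cfg = selftrain_config(),
                         batch_size = 16L, predictions = NULL) {
  stopifnot(length(pairs) == length(bboxes))
  out <- vector("list", length(pairs))
  for (start in seq(1, length(pairs), by = batch_size)) {
    ids <- start:min(start + batch_size - 1L, length(pairs))
    if (is.null(predictions)) {
      preds <- ensemble_predict(nets, lapply(pairs[ids], `[[`, "image"))
      if (length(ids) == 1L) dim(preds) <- c(dim(preds), 1L)
    } else {
      d1 <- dim(predictions[[ids[1]]])
      preds <- array(unlist(predictions[ids]), c(d1, length(ids)))
    }
    for (j in seq_along(ids)) {
      p <- preds[, , j]
      if (round_idx < cfg$erosion_rounds) p <- erode_disk1(p, cfg$erosion_conn)
      ar <- accept_or_revert(p, bboxes[[ids[j]]], cfg$iou_accept, cfg$split_col)
      m <- clip_to_bbox(ar$mask, bboxes[[ids[j]]])
      out[[ids[j]]] <- list(mask = m, provenance = "refined",
                            round = round_idx, side_accept = ar$side_accept,
                            side_iou = ar$side_iou)
    }
  }
  out
}

#' Run the full recursive self-training pipeline
#'
#' Round 0 trains the 5-fold ensemble on the bounding boxes; each later
#' round trains on the previous round's refined masks. The fold
#' partition is computed once and reused in every round; augmentation
#' is re-drawn fresh each round. After each round the masks are
#' refined with [update_masks()] and, when ground truth or an
#' evaluation set is available, IoU/DSC mean and SD are recorded.
#'
#' @param samples list of `list(volume, weak)` (e.g.
#'   [generate_phantom()] samples). A `gt` element, if present, is used
#'   only for reporting refined-mask quality, never for training.
#' @param st_cfg a [selftrain_config()].
#' @param train_cfg a [train_config()].
#' @param model_cfg a [resunet_config()].
#' @param policy optional [augmentation_policy()].
#' @param eval_set optional list of `list(volume, gt)` held-out
#'   volumes; after each round the ensemble segments them and IoU/DSC
#'   against their ground truth is recorded.
#' @param seed master seed.
#' @param run_dir optional directory; per-round refined masks (NIfTI),
#'   JSON summaries and a consolidated `metrics.csv` are written there.
#' @param verbose print progress.
#' @return list of round states, each with `round`, `masks` (records),
#'   `fits` (the fold models), `refined_report` / `eval_report`
#'   ([evaluate_masks()] results or `NULL`).
#' @export
run_pipeline <- function(samples, st_cfg = selftrain_config(),
                         train_cfg = train_config(),
                         model_cfg = resunet_config(),
                         policy = NULL, eval_set = NULL, seed = 1L,
                         run_dir = NULL, verbose = FALSE) {
  pairs <- build_slice_dataset(lapply(samples, function(s)
    list(volume = s$volume, mask = s$weak %||% s$mask, volume_id = s$volume_id %||% NULL)))
  bboxes <- lapply(pairs, `[[`, "mask")
  gts <- extract_gt_masks(samples, pairs)
  folds <- make_folds(pairs, train_cfg$n_folds, seed = derive_seed(seed, 1L))
  current <- bboxes
  rounds <- vector("list", st_cfg$n_rounds)
  for (r in seq_len(st_cfg$n_rounds) - 1L) {
    if (verbose) message(sprintf("== round %d ==", r))
    train_pairs <- pairs
    for (i in seq_along(train_pairs)) train_pairs[[i]]$mask <- current[[i]]
    fits <- train_round(train_pairs, folds, train_cfg, model_cfg, policy,
                        round_seed = derive_seed(seed, 100L + r), verbose = verbose)
    records <- update_masks(fits, pairs, bboxes, r, st_cfg,
                            batch_size = train_cfg$batch_size)
    current <- lapply(records, `[[`, "mask")
    refined_report <- if (!is.null(gts)) {
      evaluate_masks(current, gts, ids = pair_ids(pairs))
    }
    eval_report <- if (!is.null(eval_set)) {
      evaluate_round(fits, eval_set, model_cfg, train_cfg$batch_size)
    }
    rounds[[r + 1L]] <- list(round = r, masks = records, fits = fits,
                             folds = folds, refined_report = refined_report,
                             eval_report = eval_report)
    if (!is.null(run_dir)) persist_round(rounds[[r + 1L]], pairs, samples, run_dir)
    if (verbose && !is.null(refined_report)) {
      message(sprintf("round %d refined IoU %.3f +- %.3f", r,
                      refined_report$iou_mean, refined_report$iou_sd))
    }
  }
  if (!is.null(run_dir)) write_round_metrics(rounds, file.path(run_dir, "metrics.csv"))
  rounds
}

pair_ids <- function(pairs) {
  vapply(pairs, function(p) sprintf("%s_s%03d", p$volume_id, p$slice_index), character(1))
}

extract_gt_masks <- function(samples, pairs) {
  if (!all(vapply(samples, function(s) !is.null(s$gt), logical(1)))) return(NULL)
  by_vid <- setNames(lapply(samples, `[[`, "gt"),
                     vapply(seq_along(samples), function(i)
                       as.character(samples[[i]]$volume_id %||% i), character(1)))
  lapply(pairs, function(p) by_vid[[as.character(p$volume_id)]]$data[p$slice_index, , ])
}

# Segment a held-out evaluation set with the round's ensemble and score
# every carotid-bearing slice against its ground truth.
evaluate_round <- function(fits, eval_set, model_cfg, batch_size = 16L) {
  preds <- list(); gts <- list(); ids <- character(0)
  for (vi in seq_along(eval_set)) {
    ev <- eval_set[[vi]]
    ks <- which(apply(ev$gt$data, 1, function(sl) any(sl != 0)))
    if (length(ks) == 0) next
    for (start in seq(1, length(ks), by = batch_size)) {
      chunk <- ks[start:min(start + batch_size - 1L, length(ks))]
      pb <- ensemble_predict(fits, lapply(chunk, function(k)
        stack_neighbors(ev$volume, k)))
      if (length(chunk) == 1L) dim(pb) <- c(dim(pb), 1L)
      for (j in seq_along(chunk)) {
        preds[[length(preds) + 1L]] <- pb[, , j]
        gts[[length(gts) + 1L]] <- ev$gt$data[chunk[j], , ]
        ids <- c(ids, sprintf("eval%d_s%03d", vi, chunk[j]))
      }
    }
  }
  if (length(preds) == 0) return(NULL)
  evaluate_masks(preds, gts, ids = ids)
}

persist_round <- function(state, pairs, samples, run_dir) {
  rd <- file.path(run_dir, sprintf("round_%d", state$round))
  dir.create(rd, recursive = TRUE, showWarnings = FALSE)
  # reassemble refined masks into per-volume NIfTI files
  vids <- vapply(pairs, function(p) as.character(p$volume_id), character(1))
  for (vi in seq_along(samples)) {
    vid <- as.character(samples[[vi]]$volume_id %||% vi)
    sel <- which(vids == vid)
    if (length(sel) == 0) next
    arr <- array(0L, dim(samples[[vi]]$volume$data))
    for (i in sel) arr[pairs[[i]]$slice_index, , ] <- state$masks[[i]]$mask
    write_volume(mask_volume(arr, provenance = "refined"),
                 file.path(rd, sprintf("refined_%s.nii.gz", vid)))
  }
  summ <- list(round = state$round,
               accepted_left = mean(vapply(state$masks, function(m)
                 m$side_accept[1], logical(1))),
               accepted_right = mean(vapply(state$masks, function(m)
                 m$side_accept[2], logical(1))))
  if (!is.null(state$refined_report)) {
    summ$refined_iou_mean <- state$refined_report$iou_mean
    summ$refined_iou_sd <- state$refined_report$iou_sd
  }
  if (!is.null(state$eval_report)) {
    summ$eval_iou_mean <- state$eval_report$iou_mean
    summ$eval_iou_sd <- state$eval_report$iou_sd
    summ$eval_dsc_mean <- state$eval_report$dsc_mean
    summ$eval_dsc_sd <- state$eval_report$dsc_sd
  }
  jsonlite::write_json(summ, file.path(rd, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Consolidate per-round IoU/DSC metrics into one CSV table
#'
#' One row per round with IoU mean/SD and DSC mean/SD of the round's
#' evaluation (held-out set if present, else the refined-mask report).
#'
#' @param rounds result of [run_pipeline()].
#' @param path output CSV path.
#' @return the table, invisibly.
#' @export
write_round_metrics <- function(rounds, path) {
  rows <- lapply(rounds, function(st) {
    rep_ <- st$eval_report %||% st$refined_report
    data.frame(round = st$round,
               iou_mean = rep_$iou_mean %||% NA_real_,
               iou_sd = rep_$iou_sd %||% NA_real_,
               dsc_mean = rep_$dsc_mean %||% NA_real_,
               dsc_sd = rep_$dsc_sd %||% NA_real_)
  })
  tab <- do.call(rbind, rows)
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
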