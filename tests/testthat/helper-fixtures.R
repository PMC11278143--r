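# Shared fixtures: tiny configurations and independent brute-force
# oracles used across the suite. Oracles are deliberately naive
# (pixel loops) and never call package internals.

tiny_phantom_spec <- function(shape = c(16L, 32L, 32L), ...) {
  phantom_spec(shape = shape, tube_separation_px = 14, ...)
}

tiny_model_cfg <- function(...) {
  resunet_config(input_size = c(32L, 32L), levels = 5L, base_filters = 4L,
                 bottleneck_filters = 64L, dropout_p = 0.2, ...)
}

tiny_train_cfg <- function(...) {
  train_config(lr0 = 1e-3, max_epochs = 6L, patience = 3L, batch_size = 8L, ...)
}

rand_mask <- function(h, w, p = 0.3) {
  matrix(rbinom(h * w, 1, p), h, w)
}

# -- naive pixel-loop oracles ------------------------------------------------

naive_iou <- function(a, b) {
  inter <- 0; uni <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    av <- a[i, j] != 0; bv <- b[i, j] != 0
    if (av && bv) inter <- inter + 1
    if (av || bv) uni <- uni + 1
  }
  if (uni == 0) 1 else inter / uni
}

naive_erode <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  at <- function(i, j) if (i < 1 || i > H || j < 1 || j > W) 0L else (m[i, j] != 0) * 1L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (at(i, j) && at(i - 1, j) && at(i + 1, j) && at(i, j - 1) && at(i, j + 1)) {
      out[i, j] <- 1L
    }
  }
  out
}

# erode (if round < erosion_rounds) -> per-side IoU gate -> clip to bbox
naive_update <- function(pred, bbox, round_idx, erosion_rounds = 4L, gate = 0.5) {
  p <- if (round_idx < erosion_rounds) naive_erode(pred) else (pred != 0) * 1L
  W <- ncol(p); sc <- W %/% 2
  out <- matrix(0L, nrow(p), W)
  for (side in 1:2) {
    cols <- if (side == 1) seq_len(sc) else (sc + 1):W
    ps <- p[, cols, drop = FALSE]; bs <- bbox[, cols, drop = FALSE]
    keep <- if (naive_iou(ps, bs) >= gate) ps else bs
    out[, cols] <- keep
  }
  for (i in seq_len(nrow(out))) for (j in seq_len(W)) {
    if (bbox[i, j] == 0) out[i, j] <- 0L
  }
  out
}

# Wrap plain matrices as the pair/bbox structures update_masks expects.
mask_fixture_pairs <- function(masks) {
  lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    list(image = array(0.5, c(nrow(m), ncol(m), 3L)), mask = m,
         volume_id = 1L, slice_index = i, provenance = "bbox")
  })
}
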