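#' Residual U-net configuration
#'
#' Describes the segmentation network: a 5-level encoder-decoder on
#' pseudo-RGB input. Each level applies two padded 3x3 stride-1
#' convolutions, each followed by batch normalisation and a PReLU, with
#' an additive residual shortcut across the convolution pair (1x1
#' projection when the channel count changes); 2x2 average pooling
#' halves the spatial dimensions between encoder levels while the
#' feature channels double. The bottleneck level has
#' `bottleneck_filters` channels (1000 at the reference 240x240 scale).
#' The decoder mirrors the encoder with nearest-neighbour 2x
#' upsampling and concatenation of the matching encoder features. A
#' 1x1 convolution plus sigmoid yields per-pixel probabilities,
#' thresholded at `prob_threshold` for the final classification.
#' Channel dropout at `dropout_p` regularises every block.
#'
#' One code path serves both the full-scale instance (240x240 input,
#' 1000-filter bottleneck) and small test-scale instances (e.g. 32x32
#' input, 64-filter bottleneck).
#'
#' @param input_size `(H, W)`, each divisible by `2^(levels - 1)`.
#' @param levels number of resolution levels (default 5).
#' @param base_filters channels of the first encoder level; levels
#'   double from here.
#' @param bottleneck_filters channels of the deepest level; defaults to
#'   the doubling rule `base_filters * 2^(levels - 1)`, overridden to
#'   1000 at reference scale.
#' @param dropout_p channel dropout rate (reference value 0.6).
#' @param prob_threshold probability threshold for binarization.
#' @return a `resunet_config` list.
#' @export
resunet_config <- function(input_size = c(240L, 240L), levels = 5L,
                           base_filters = 64L,
                           bottleneck_filters = 1000L,
                           dropout_p = 0.6, prob_threshold = 0.5) {
  cfg <- list(input_size = as.integer(input_size), levels = as.integer(levels),
              base_filters = as.integer(base_filters),
              bottleneck_filters = as.integer(bottleneck_filters %||%
                                                (base_filters * 2^(levels - 1))),
              dropout_p = dropout_p, prob_threshold = prob_threshold)
  div <- 2^(cfg$levels - 1)
  if (any(cfg$input_size %% div != 0)) {
    stopf("resunet_config: input size %s not divisible by 2^%d = %d",
          paste(cfg$input_size, collapse = "x"), cfg$levels - 1, div)
  }
  if (cfg$dropout_p < 0 || cfg$dropout_p >= 1) stopf("resunet_config: dropout_p must be in [0, 1)")
  if (cfg$prob_threshold <= 0 || cfg$prob_threshold >= 1) {
    stopf("resunet_config: prob_threshold must be in (0, 1)")
  }
  class(cfg) <- "resunet_config"
  cfg
}

resunet_filters <- function(cfg) {
  f <- cfg$base_filters * 2^(seq_len(cfg$levels - 1) - 1)
  c(f, cfg$bottleneck_filters)
}

#' Build a residual U-net
#'
#' Instantiates the network described by a [resunet_config()]:
#' parameters are He-initialised from `seed`, so two builds from the
#' same config and seed are identical.
#'
#' @param cfg a [resunet_config()].
#' @param seed integer seed for weight initialisation.
#' @return a `resunet` object (list of `cfg`, flat `params`, batch-norm
#'   `state`).
#' @export
build_model <- function(cfg, seed = 1L) {
  set.seed(seed)
  f <- resunet_filters(cfg)
  L <- cfg$levels
  params <- list(); state <- list()
  cin <- 3L
  for (i in seq_len(L - 1)) {
    params <- c(params, prefix_names(init_block_params(cin, f[i]), paste0("enc", i)))
    state <- c(state, prefix_names(init_block_state(f[i]), paste0("enc", i)))
    cin <- f[i]
  }
  params <- c(params, prefix_names(init_block_params(f[L - 1], f[L]), "bott"))
  state <- c(state, prefix_names(init_block_state(f[L]), "bott"))
  up <- f[L]
  for (i in rev(seq_len(L - 1))) {
    params <- c(params, prefix_names(init_block_params(up + f[i], f[i]), paste0("dec", i)))
    state <- c(state, prefix_names(init_block_state(f[i]), paste0("dec", i)))
    up <- f[i]
  }
  params$head.w <- array(rnorm(f[1], 0, sqrt(2 / f[1])), c(1L, 1L, f[1], 1L))
  params$head.b <- numeric(1)
  structure(list(cfg = cfg, params = params, state = state, seed = as.integer(seed)),
            class = "resunet")
}

#' @export
print.resunet <- function(x, ...) {
  cat(sprintf("resunet %s input | levels %d | filters %s | %d parameters\n",
              paste(x$cfg$input_size, collapse = "x"), x$cfg$levels,
              paste(resunet_filters(x$cfg), collapse = "/"),
              count_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a network
#' @param net a `resunet`.
#' @return integer parameter count.
#' @export
count_params <- function(net) {
  sum(vapply(net$params, length, numeric(1)))
}

subset_params <- function(params, prefix) {
  sel <- startsWith(names(params), paste0(prefix, "."))
  out <- params[sel]
  names(out) <- substring(names(out), nchar(prefix) + 2L)
  out
}

# Full forward pass. x: (H, W, 3, N). Returns probabilities (H, W, 1, N),
# a cache for backward, and (in training) updated batch-norm state.
resunet_fwd <- function(net, x, train = FALSE) {
  cfg <- net$cfg
  L <- cfg$levels
  p <- net$params; st <- net$state
  caches <- list(); skips <- list(); pools <- list()
  h <- x
  for (i in seq_len(L - 1)) {
    bk <- block_fwd(h, subset_params(p, paste0("enc", i)),
                    subset_params(st, paste0("enc", i)), train, cfg$dropout_p)
    st[paste0("enc", i, ".", names(bk$state))] <- bk$state
    caches[[paste0("enc", i)]] <- bk$cache
    skips[[i]] <- bk$out
    pl <- avgpool2_fwd(bk$out)
    pools[[i]] <- pl$cache
    h <- pl$out
  }
  bk <- block_fwd(h, subset_params(p, "bott"), subset_params(st, "bott"),
                  train, cfg$dropout_p)
  st[paste0("bott.", names(bk$state))] <- bk$state
  caches$bott <- bk$cache
  h <- bk$out
  ups <- list()
  for (i in rev(seq_len(L - 1))) {
    us <- upsample2_fwd(h)
    ups[[paste0("dec", i)]] <- us$cache
    cat_in <- abind4(us$out, skips[[i]])
    bk <- block_fwd(cat_in, subset_params(p, paste0("dec", i)),
                    subset_params(st, paste0("dec", i)), train, cfg$dropout_p)
    st[paste0("dec", i, ".", names(bk$state))] <- bk$state
    caches[[paste0("dec", i)]] <- bk$cache
    caches[[paste0("dec", i, ".ncat")]] <- dim(us$out)[3]
    h <- bk$out
  }
  hd <- conv_fwd_l(h, p$head.w, p$head.b)
  prob <- sigmoid(hd$out)
  list(prob = prob, state = st,
       cache = list(blocks = caches, pools = pools, ups = ups, head = hd$cache,
                    prob = prob))
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Backward pass from d(loss)/d(prob). Returns flat gradient list.
resunet_bwd <- function(net, cache, gprob) {
  cfg <- net$cfg
  L <- cfg$levels
  gz <- gprob * cache$prob * (1 - cache$prob)
  hd <- conv_bwd_l(cache$head, gz)
  grads <- list(head.w = hd$gw, head.b = hd$gb)
  g <- hd$gx
  gskips <- vector("list", L - 1)
  for (i in seq_len(L - 1)) {
    bb <- block_bwd(cache$blocks[[paste0("dec", i)]], g)
    grads <- c(grads, prefix_names(bb$grads, paste0("dec", i)))
    ncat <- cache$blocks[[paste0("dec", i, ".ncat")]]
    gup <- bb$gx[, , seq_len(ncat), , drop = FALSE]
    gskips[[i]] <- bb$gx[, , ncat + seq_len(dim(bb$gx)[3] - ncat), , drop = FALSE]
    g <- upsample2_bwd(cache$ups[[paste0("dec", i)]], gup)
  }
  bb <- block_bwd(cache$blocks$bott, g)
  grads <- c(grads, prefix_names(bb$grads, "bott"))
  g <- bb$gx
  for (i in rev(seq_len(L - 1))) {
    g <- avgpool2_bwd(cache$pools[[i]], g) + gskips[[i]]
    bb <- block_bwd(cache$blocks[[paste0("enc", i)]], g)
    grads <- c(grads, prefix_names(bb$grads, paste0("enc", i)))
    g <- bb$gx
  }
  grads
}

#' Predict segmentation probabilities for a batch of pseudo-RGB slices
#'
#' Runs the network in inference mode: no dropout sampling, batch
#' normalisation using its accumulated running statistics, so repeated
#' calls on the same input are identical.
#'
#' @param net a `resunet` from [build_model()].
#' @param batch either one `H x W x 3` pseudo-RGB slice, a list of
#'   them, or an `(H, W, 3, N)` array.
#' @return an `(H, W, N)` array of probabilities in `(0, 1)` (a single
#'   `H x W` matrix if a single slice was given).
#' @export
predict_proba <- function(net, batch) {
  single <- FALSE
  if (is.list(batch)) {
    batch <- array(unlist(batch), c(dim(batch[[1]]), length(batch)))
  } else if (length(dim(batch)) == 3L) {
    dim(batch) <- c(dim(batch), 1L)
    single <- TRUE
  }
  hw <- net$cfg$input_size
  if (!identical(as.integer(dim(batch)[1:3]), c(hw, 3L))) {
    stopf("predict_proba: batch shape %s does not match config %sx3",
          paste(dim(batch)[1:3], collapse = "x"), paste(hw, collapse = "x"))
  }
  fw <- resunet_fwd(net, batch, train = FALSE)
  p <- fw$prob
  dim(p) <- dim(p)[c(1, 2, 4)]
  if (single) p[, , 1] else p
}

#' Threshold a probability map into a binary mask
#'
#' A pixel is foreground iff its probability is `>= threshold`
#' (inclusive at the boundary).
#'
#' @param p numeric array of probabilities in `[0, 1]`.
#' @param threshold scalar threshold (default 0.5).
#' @return integer 0/1 array of the same shape.
#' @export
binarize <- function(p, threshold = 0.5) {
  out <- array(as.integer(p >= threshold), dim(p) %||% length(p))
  if (is.null(dim(p))) out <- as.integer(out)
  out
}
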