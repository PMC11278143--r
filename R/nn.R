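# Internal neural-network layers. All activations are (H, W, C, N)
# double arrays; every layer returns list(out, cache) in the forward
# pass and consumes (cache, gout) in the backward pass. Convolutions
# run through the compiled im2col kernels; everything else is plain R.

channel_mat <- function(x) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  attr(m, "hwcn") <- d
  m
}

channel_unmat <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

conv_fwd_l <- function(x, w, b) {
  list(out = conv2d_fwd(x, w, b), cache = list(x = x, w = w))
}

conv_bwd_l <- function(cache, gy) {
  g <- conv2d_bwd(cache$x, cache$w, gy)
  list(gx = g$gx, gw = g$gw, gb = g$gb)
}

bn_fwd <- function(x, gamma, beta, run_mean, run_var, train, momentum = 0.9, eps = 1e-5) {
  d <- dim(x)
  m <- channel_mat(x)
  if (train) {
    mu <- colMeans(m)
    xc <- sweep(m, 2, mu)
    v <- colMeans(xc * xc)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean
    v <- run_var
    xc <- sweep(m, 2, mu)
  }
  sdv <- sqrt(v + eps)
  xhat <- sweep(xc, 2, sdv, "/")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = channel_unmat(y, d),
       cache = list(xhat = xhat, sdv = sdv, gamma = gamma, d = d, train = train),
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(cache, gy) {
  d <- cache$d
  g <- channel_mat(gy)
  xhat <- cache$xhat
  m <- nrow(g)
  ggamma <- colSums(g * xhat)
  gbeta <- colSums(g)
  if (cache$train) {
    t1 <- sweep(g, 2, gbeta / m)
    t2 <- sweep(xhat, 2, ggamma / m, "*")
    gx <- sweep(t1 - t2, 2, cache$gamma / cache$sdv, "*")
  } else {
    gx <- sweep(g, 2, cache$gamma / cache$sdv, "*")
  }
  list(gx = channel_unmat(gx, d), ggamma = ggamma, gbeta = gbeta)
}

prelu_fwd <- function(x, a) {
  d <- dim(x)
  m <- channel_mat(x)
  neg <- pmin(m, 0)
  y <- pmax(m, 0) + sweep(neg, 2, a, "*")
  list(out = channel_unmat(y, d), cache = list(m = m, a = a, d = d))
}

prelu_bwd <- function(cache, gy) {
  d <- cache$d
  g <- channel_mat(gy)
  pos <- cache$m > 0
  ga <- colSums(g * pmin(cache$m, 0))
  gx <- g * pos + sweep(g * (!pos), 2, cache$a, "*")
  list(gx = channel_unmat(gx, d), ga = ga)
}

avgpool2_fwd <- function(x) {
  d <- dim(x)
  io <- seq(1, d[1], by = 2); jo <- seq(1, d[2], by = 2)
  y <- (x[io, , , , drop = FALSE] + x[io + 1, , , , drop = FALSE])[, jo, , , drop = FALSE] +
       (x[io, , , , drop = FALSE] + x[io + 1, , , , drop = FALSE])[, jo + 1, , , drop = FALSE]
  list(out = y * 0.25, cache = list(d = d))
}

avgpool2_bwd <- function(cache, gy) {
  d <- cache$d
  h2 <- d[1] %/% 2; w2 <- d[2] %/% 2
  gy[rep(seq_len(h2), each = 2), rep(seq_len(w2), each = 2), , , drop = FALSE] * 0.25
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  list(out = x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE],
       cache = list(d = d))
}

upsample2_bwd <- function(cache, gy) {
  io <- seq(1, nrow(gy), by = 2); jo <- seq(1, dim(gy)[2], by = 2)
  (gy[io, , , , drop = FALSE] + gy[io + 1, , , , drop = FALSE])[, jo, , , drop = FALSE] +
  (gy[io, , , , drop = FALSE] + gy[io + 1, , , , drop = FALSE])[, jo + 1, , , drop = FALSE]
}

# spatially-shared (channel) dropout: drops whole feature maps per sample
dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, cache = list(mask = NULL)))
  d <- dim(x)
  keep <- array(stats::rbinom(d[3] * d[4], 1, 1 - p), c(d[3], d[4])) / (1 - p)
  mask <- array(keep[rep(seq_len(d[3]), each = d[1] * d[2]) +
                       d[3] * rep(seq_len(d[4]) - 1, each = d[1] * d[2] * d[3])], d)
  list(out = x * mask, cache = list(mask = mask))
}

dropout_bwd <- function(cache, gy) {
  if (is.null(cache$mask)) gy else gy * cache$mask
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- residual block: conv-BN-PReLU, conv-BN, +shortcut, PReLU, dropout ----

init_block_params <- function(cin, cout, k = 3L) {
  he <- function(kk, ci, co) array(rnorm(kk * kk * ci * co, 0, sqrt(2 / (kk * kk * ci))),
                                   c(kk, kk, ci, co))
  p <- list(conv1.w = he(k, cin, cout), conv1.b = numeric(cout),
            bn1.gamma = rep(1, cout), bn1.beta = numeric(cout),
            prelu1.a = rep(0.25, cout),
            conv2.w = he(k, cout, cout), conv2.b = numeric(cout),
            bn2.gamma = rep(1, cout), bn2.beta = numeric(cout),
            prelu2.a = rep(0.25, cout))
  if (cin != cout) {
    p$proj.w <- he(1L, cin, cout)
    p$proj.b <- numeric(cout)
  }
  p
}

init_block_state <- function(cout) {
  list(bn1.mean = numeric(cout), bn1.var = rep(1, cout),
       bn2.mean = numeric(cout), bn2.var = rep(1, cout))
}

block_fwd <- function(x, p, st, train, dropout_p) {
  c1 <- conv_fwd_l(x, p$conv1.w, p$conv1.b)
  b1 <- bn_fwd(c1$out, p$bn1.gamma, p$bn1.beta, st$bn1.mean, st$bn1.var, train)
  a1 <- prelu_fwd(b1$out, p$prelu1.a)
  c2 <- conv_fwd_l(a1$out, p$conv2.w, p$conv2.b)
  b2 <- bn_fwd(c2$out, p$bn2.gamma, p$bn2.beta, st$bn2.mean, st$bn2.var, train)
  if (!is.null(p$proj.w)) {
    pr <- conv_fwd_l(x, p$proj.w, p$proj.b)
    res <- pr$out
  } else {
    pr <- NULL
    res <- x
  }
  s <- b2$out + res
  a2 <- prelu_fwd(s, p$prelu2.a)
  dr <- dropout_fwd(a2$out, dropout_p, train)
  st$bn1.mean <- b1$run_mean; st$bn1.var <- b1$run_var
  st$bn2.mean <- b2$run_mean; st$bn2.var <- b2$run_var
  list(out = dr$out, state = st,
       cache = list(c1 = c1$cache, b1 = b1$cache, a1 = a1$cache,
                    c2 = c2$cache, b2 = b2$cache, pr = if (is.null(pr)) NULL else pr$cache,
                    a2 = a2$cache, dr = dr$cache, has_proj = !is.null(p$proj.w)))
}

block_bwd <- function(cache, gy) {
  g <- dropout_bwd(cache$dr, gy)
  pa2 <- prelu_bwd(cache$a2, g)
  gs <- pa2$gx
  gb2 <- bn_bwd(cache$b2, gs)
  gc2 <- conv_bwd_l(cache$c2, gb2$gx)
  pa1 <- prelu_bwd(cache$a1, gc2$gx)
  gb1 <- bn_bwd(cache$b1, pa1$gx)
  gc1 <- conv_bwd_l(cache$c1, gb1$gx)
  gx <- gc1$gx
  grads <- list(conv1.w = gc1$gw, conv1.b = gc1$gb,
                bn1.gamma = gb1$ggamma, bn1.beta = gb1$gbeta,
                prelu1.a = pa1$ga,
                conv2.w = gc2$gw, conv2.b = gc2$gb,
                bn2.gamma = gb2$ggamma, bn2.beta = gb2$gbeta,
                prelu2.a = pa2$ga)
  if (cache$has_proj) {
    gpr <- conv_bwd_l(cache$pr, gs)
    grads$proj.w <- gpr$gw
    grads$proj.b <- gpr$gb
    gx <- gx + gpr$gx
  } else {
    gx <- gx + gs
  }
  list(gx = gx, grads = grads)
}

prefix_names <- function(lst, prefix) {
  names(lst) <- paste0(prefix, ".", names(lst))
  lst
}
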