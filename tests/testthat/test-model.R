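test_that("network outputs per-pixel probabilities of the input spatial shape", {
  cfg <- tiny_model_cfg()
  net <- build_model(cfg, seed = 1)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  p <- predict_proba(net, x)
  expect_equal(dim(p), c(32L, 32L))
  expect_true(all(p > 0 & p < 1))
  # batch form
  xb <- array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  pb <- predict_proba(net, xb)
  expect_equal(dim(pb), c(32L, 32L, 4L))
  # all-zero input gives finite probabilities
  p0 <- predict_proba(net, array(0, c(32, 32, 3)))
  expect_true(all(is.finite(p0)))
  expect_error(predict_proba(net, array(0, c(16, 16, 3))), "does not match")
})

test_that("builds are deterministic in the seed and deepest map is input/2^4", {
  cfg <- tiny_model_cfg()
  a <- build_model(cfg, seed = 3)
  b <- build_model(cfg, seed = 3)
  expect_identical(a$params, b$params)
  # encoder channels double per level while spatial dims halve
  filters <- carotidseg:::resunet_filters(cfg)
  expect_equal(filters, c(4, 8, 16, 32, 64))
  expect_equal(32 / 2^(cfg$levels - 1), 2)  # deepest feature map 2x2 for 32x32
  cfg240 <- resunet_config(input_size = c(240, 240))
  expect_equal(carotidseg:::resunet_filters(cfg240), c(64, 128, 256, 512, 1000))
  expect_equal(240 / 2^4, 15)  # 15x15 bottleneck at reference scale
  expect_error(resunet_config(input_size = c(30, 30)), "divisible")
})

test_that("parameter count increases strictly with bottleneck width", {
  counts <- vapply(c(16L, 32L, 64L), function(bf) {
    count_params(build_model(resunet_config(input_size = c(32, 32), base_filters = 4L,
                                            bottleneck_filters = bf), seed = 1))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("inference is deterministic and training mode samples dropout", {
  net <- build_model(tiny_model_cfg(), seed = 2)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  p1 <- predict_proba(net, x)
  p2 <- predict_proba(net, x)
  expect_identical(p1, p2)
  set.seed(1)
  t1 <- carotidseg:::resunet_fwd(net, x, train = TRUE)$prob
  t2 <- carotidseg:::resunet_fwd(net, x, train = TRUE)$prob
  expect_false(identical(t1, t2))  # dropout masks differ between draws
})

test_that("gradient flows to every parameter through the residual wiring", {
  cfg <- resunet_config(input_size = c(16, 16), levels = 3L, base_filters = 3L,
                        bottleneck_filters = 12L, dropout_p = 0)
  net <- build_model(cfg, seed = 4)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.2), c(16, 16, 1, 2))
  fw <- carotidseg:::resunet_fwd(net, x, train = TRUE)
  dl <- carotidseg:::dice_loss_batch(fw$prob, y)
  gr <- carotidseg:::resunet_bwd(net, fw$cache, dl$grad)
  expect_setequal(names(gr), names(net$params))
  nonzero <- vapply(gr, function(g) any(g != 0), logical(1))
  expect_true(all(nonzero))
})

test_that("backward pass matches finite differences", {
  cfg <- resunet_config(input_size = c(8, 8), levels = 2L, base_filters = 3L,
                        bottleneck_filters = 6L, dropout_p = 0)
  net <- build_model(cfg, seed = 5)
  x <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  gy <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  fw <- carotidseg:::resunet_fwd(net, x, train = TRUE)
  gr <- carotidseg:::resunet_bwd(net, fw$cache, gy)
  f <- function(params) {
    n2 <- net; n2$params <- params
    sum(carotidseg:::resunet_fwd(n2, x, train = TRUE)$prob * gy)
  }
  base <- f(net$params)
  eps <- 1e-6
  set.seed(6)
  for (nm in sample(names(net$params), 8)) {
    i <- sample(length(net$params[[nm]]), 1)
    p2 <- net$params
    p2[[nm]][i] <- p2[[nm]][i] + eps
    fd <- (f(p2) - base) / eps
    expect_equal(gr[[nm]][i], fd, tolerance = 1e-3)
  }
})

test_that("binarize uses an inclusive threshold and is idempotent", {
  expect_identical(binarize(matrix(0.5, 2, 2)), matrix(1L, 2, 2))
  expect_identical(binarize(c(0.49, 0.51)), c(0L, 1L))
  p <- matrix(runif(16), 4, 4)
  expect_identical(binarize(binarize(p)), binarize(p))
})
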