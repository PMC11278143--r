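#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from one master seed through this
#' counter-based derivation, so that every component (phantom volumes,
#' fold shuffles, weight initialisation, augmentation draws) is
#' reproducible and independently re-seedable. The derivation is a small
#' multiplicative-congruential mix kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param ... integer counters identifying the consumer (e.g. volume
#'   index, round index, fold index).
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  counters <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in counters) {
    s <- (s * 69069 + as.double(k) * 40503 + 12345) %% 2147483647
  }
  as.integer(s)
}

#' Round half away from zero
#'
#' Deterministic half-up rounding used for copy counts and voxel-grid
#' shapes (base `round()` rounds half to even).
#' @param x numeric vector.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' Population standard deviation
#' @param x numeric vector.
#' @keywords internal
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
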