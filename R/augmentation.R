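#' Augmentation policy
#'
#' The set of random transforms applied to slice pairs during training,
#' each with its own application probability. Geometric transforms
#' (rotation, flips, shift, zoom) are applied to the image and the mask
#' with identical parameters; the mask is interpolated
#' nearest-neighbour so it stays binary. Intensity transforms
#' (contrast, gamma, blur, noise) touch only the image.
#'
#' Defaults are the pipeline's reference values: rotation up to 15
#' degrees with p = 0.9, horizontal and vertical flips p = 0.5,
#' contrast p = 0.8, gamma p = 0.5, 3x3 blur p = 0.05, Gaussian noise
#' p = 0.05, shift/zoom p = 0.5. The transform amplitude ranges are
#' package choices (see the methods vignette) and fully configurable.
#'
#' @param rotation_max_deg maximum absolute rotation in degrees.
#' @param rotation_p,hflip_p,vflip_p,contrast_p,gamma_p,blur_p,noise_p,shift_zoom_p
#'   per-transform application probabilities, all in `[0, 1]`.
#' @param contrast_range,gamma_range multiplicative factor ranges.
#' @param blur_kernel odd blur kernel size (3 = the 3x3 kernel).
#' @param noise_sigma SD of additive Gaussian image noise.
#' @param shift_max_frac max shift as a fraction of the image extent.
#' @param zoom_range multiplicative zoom factor range.
#' @return an `augmentation_policy` list.
#' @export
augmentation_policy <- function(rotation_max_deg = 15, rotation_p = 0.9,
                                hflip_p = 0.5, vflip_p = 0.5,
                                contrast_p = 0.8, contrast_range = c(0.8, 1.2),
                                gamma_p = 0.5, gamma_range = c(0.8, 1.2),
                                blur_p = 0.05, blur_kernel = 3L,
                                noise_p = 0.05, noise_sigma = 0.01,
                                shift_zoom_p = 0.5, shift_max_frac = 0.1,
                                zoom_range = c(0.9, 1.1)) {
  p <- list(rotation_max_deg = rotation_max_deg, rotation_p = rotation_p,
            hflip_p = hflip_p, vflip_p = vflip_p,
            contrast_p = contrast_p, contrast_range = contrast_range,
            gamma_p = gamma_p, gamma_range = gamma_range,
            blur_p = blur_p, blur_kernel = as.integer(blur_kernel),
            noise_p = noise_p, noise_sigma = noise_sigma,
            shift_zoom_p = shift_zoom_p, shift_max_frac = shift_max_frac,
            zoom_range = zoom_range)
  probs <- unlist(p[grepl("_p$", names(p))])
  if (any(probs < 0 | probs > 1)) stopf("augmentation_policy: probabilities must be in [0, 1]")
  if (rotation_max_deg <= 0) stopf("augmentation_policy: rotation_max_deg must be > 0")
  class(p) <- "augmentation_policy"
  p
}

#' Stratify slice pairs by mask area
#'
#' Splits the dataset at the mean plus one (population) standard
#' deviation of the per-slice mask pixel counts: pairs at or below the
#' threshold form the small-area stratum, the rest the big-area
#' stratum. Small, near-circular carotid sections dominate the data;
#' the big stratum holds the rarer large/oblique sections that would
#' otherwise be under-represented under uniform augmentation.
#'
#' @param pairs non-empty list of `slice_pair`s.
#' @return an `area_stratification`: list with `threshold`, `areas`,
#'   `small_ids`, `big_ids`, `multiplier_small` (1.3), `multiplier_big` (7).
#' @export
stratify_by_area <- function(pairs) {
  if (length(pairs) == 0) stopf("stratify_by_area: empty dataset")
  areas <- vapply(pairs, function(p) sum(p$mask != 0), numeric(1))
  threshold <- mean(areas) + pop_sd(areas)
  small <- which(areas <= threshold)
  structure(list(threshold = threshold, areas = areas,
                 small_ids = small, big_ids = setdiff(seq_along(pairs), small),
                 multiplier_small = 1.3, multiplier_big = 7.0),
            class = "area_stratification")
}

# Inverse-mapped affine warp about the image center:
# forward model = zoom, then rotation, then shift (pixels).
# image: bilinear, outside -> 0; mask: nearest-neighbour, outside -> 0.
affine_warp <- function(img, angle_deg, shift_rc, zoom, nearest = FALSE) {
  H <- dim(img)[1]; W <- dim(img)[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  th <- -angle_deg * pi / 180
  out_r <- matrix(seq_len(H), H, W) - cy - shift_rc[1]
  out_c <- matrix(seq_len(W), H, W, byrow = TRUE) - cx - shift_rc[2]
  src_r <- (cos(th) * out_r - sin(th) * out_c) / zoom + cy
  src_c <- (sin(th) * out_r + cos(th) * out_c) / zoom + cx
  sample_plane <- function(pl) {
    if (nearest) {
      ri <- round_half_up(src_r); ci <- round_half_up(src_c)
      ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
      val <- matrix(0, H, W)
      val[ok] <- pl[cbind(ri[ok], ci[ok])]
      val
    } else {
      r0 <- floor(src_r); c0 <- floor(src_c)
      fr <- src_r - r0; fc <- src_c - c0
      val <- matrix(0, H, W)
      for (dr in 0:1) for (dcl in 0:1) {
        rr <- r0 + dr; cc <- c0 + dcl
        ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
        w <- (if (dr == 0) 1 - fr else fr) * (if (dcl == 0) 1 - fc else fc)
        contrib <- matrix(0, H, W)
        contrib[ok] <- pl[cbind(rr[ok], cc[ok])] * w[ok]
        val <- val + contrib
      }
      val
    }
  }
  if (length(dim(img)) == 3L) {
    out <- array(0, dim(img))
    for (ch in seq_len(dim(img)[3])) out[, , ch] <- sample_plane(img[, , ch])
    out
  } else {
    sample_plane(img)
  }
}

blur3 <- function(pl, k = 3L) {
  # normalized Gaussian kernel (sigma 0.8 for the 3x3 case)
  half <- (k - 1L) %/% 2L
  g <- exp(-(seq(-half, half))^2 / (2 * 0.8^2))
  ker <- outer(g, g); ker <- ker / sum(ker)
  H <- nrow(pl); W <- ncol(pl)
  pad <- matrix(0, H + 2 * half, W + 2 * half)
  pad[half + seq_len(H), half + seq_len(W)] <- pl
  # replicate edges
  pad[seq_len(half), ] <- pad[rep(half + 1L, half), ]
  pad[H + half + seq_len(half), ] <- pad[rep(H + half, half), ]
  pad[, seq_len(half)] <- pad[, rep(half + 1L, half)]
  pad[, W + half + seq_len(half)] <- pad[, rep(W + half, half)]
  out <- matrix(0, H, W)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    out <- out + ker[i, j] * pad[(i - 1L) + seq_len(H), (j - 1L) + seq_len(W)]
  }
  out
}

# Apply one random draw of the policy to a slice pair.
augment_pair <- function(pair, policy) {
  img <- pair$image; msk <- pair$mask
  # geometric: compose rotation + shift + zoom into a single warp
  angle <- if (runif(1) < policy$rotation_p)
    runif(1, -policy$rotation_max_deg, policy$rotation_max_deg) else 0
  do_sz <- runif(1) < policy$shift_zoom_p
  shift <- if (do_sz) c(runif(1, -1, 1), runif(1, -1, 1)) *
      policy$shift_max_frac * dim(msk) else c(0, 0)
  zoom <- if (do_sz) runif(1, policy$zoom_range[1], policy$zoom_range[2]) else 1
  if (angle != 0 || any(shift != 0) || zoom != 1) {
    img <- affine_warp(img, angle, shift, zoom, nearest = FALSE)
    msk <- affine_warp(msk, angle, shift, zoom, nearest = TRUE)
  }
  if (runif(1) < policy$hflip_p) {
    img <- img[, rev(seq_len(ncol(msk))), , drop = FALSE]
    msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  }
  if (runif(1) < policy$vflip_p) {
    img <- img[rev(seq_len(nrow(msk))), , , drop = FALSE]
    msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
  }
  # intensity (image only)
  if (runif(1) < policy$contrast_p) {
    f <- runif(1, policy$contrast_range[1], policy$contrast_range[2])
    m <- mean(img)
    img <- m + (img - m) * f
  }
  if (runif(1) < policy$gamma_p) {
    g <- runif(1, policy$gamma_range[1], policy$gamma_range[2])
    img <- pmin(pmax(img, 0), 1)^g
  }
  if (runif(1) < policy$blur_p) {
    for (ch in seq_len(dim(img)[3])) img[, , ch] <- blur3(img[, , ch], policy$blur_kernel)
  }
  if (runif(1) < policy$noise_p) {
    img <- img + array(rnorm(length(img), 0, policy$noise_sigma), dim(img))
  }
  img <- pmin(pmax(img, 0), 1)
  out <- pair
  out$image <- img
  out$mask <- msk
  out$augmented <- TRUE
  out
}

#' Augment a subset of slice pairs to a target multiplier
#'
#' Returns all originals plus `round((multiplier - 1) * n)` augmented
#' copies (half-up rounding, so 1.3x of 10 pairs is 13), the copies
#' drawn round-robin over the subset. Each copy applies each transform
#' of the policy independently with its stated probability.
#'
#' @param pairs list of `slice_pair`s.
#' @param policy an [augmentation_policy()].
#' @param multiplier target size multiplier, `>= 1`.
#' @param seed optional seed for the random draws.
#' @return list of `slice_pair`s of length `round(multiplier * n)`.
#' @export
augment_subset <- function(pairs, policy, multiplier, seed = NULL) {
  if (multiplier < 1) stopf("augment_subset: multiplier must be >= 1, got %g", multiplier)
  if (!is.null(seed)) set.seed(seed)
  n <- length(pairs)
  if (n == 0) return(list())
  n_aug <- as.integer(round_half_up((multiplier - 1) * n))
  src <- rep(seq_len(n), length.out = n_aug)
  c(pairs, lapply(src, function(i) augment_pair(pairs[[i]], policy)))
}

#' Area-stratified dataset augmentation
#'
#' Inflates the big-area stratum 7x and the small-area stratum 1.3x
#' (the strata and multipliers coming from [stratify_by_area()]), so
#' that rare large/oblique carotid sections are heavily oversampled.
#' Re-run fresh at every self-training round.
#'
#' @param pairs the full list of `slice_pair`s.
#' @param strat an [stratify_by_area()] result computed from `pairs`.
#' @param policy an [augmentation_policy()].
#' @param seed optional seed for reproducible draws.
#' @return concatenation of the augmented small and big strata.
#' @export
augment_dataset <- function(pairs, strat, policy, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  c(augment_subset(pairs[strat$small_ids], policy, strat$multiplier_small),
    augment_subset(pairs[strat$big_ids], policy, strat$multiplier_big))
}
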