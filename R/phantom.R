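#' Specification of a synthetic two-tube phantom volume
#'
#' Parametric description of a phantom that emulates the appearance of
#' the paired carotid arteries in axial T1-weighted slices: two roughly
#' parallel dark tubes (low signal lumen) running along the slice axis,
#' each wrapped in a thin bright ring (perivascular fat), embedded in a
#' mid-intensity background (muscle), with additive Gaussian noise.
#' Tube centerlines wobble sinusoidally in-plane so that some axial
#' cross-sections cut the tube obliquely and present larger, elongated
#' areas -- reproducing the small-section / oblique-section area
#' dichotomy seen between the C1 and C2--C3 portions of real carotids.
#'
#' Intensities are on the unit scale and must satisfy
#' `tube < background < fat_ring` (dark vessel in brighter surround).
#' At the package's 1 px = 1 mm convention the default radius of 2.5 px
#' corresponds to a 5 mm artery diameter, the middle of the typical
#' 4--6 mm range.
#'
#' @param shape integer `(S, H, W)`: slices, rows, columns.
#' @param tube_radius_px tube radius in pixels (default 2.5).
#' @param tube_separation_px distance between the two tube centers.
#' @param centerline_wobble_amp in-plane wobble amplitude in pixels.
#' @param centerline_wobble_period wobble period in slices.
#' @param tube_intensity,background_intensity,fat_ring_intensity unit-scale
#'   intensities, strictly increasing in that order.
#' @param noise_sigma SD of additive Gaussian noise (unit scale).
#' @param bbox_margin_px dilation of each tube's tight per-slice box.
#' @param bbox_jitter_px max absolute integer shift applied per slice to
#'   each box (emulating annotator looseness).
#' @param seed integer seed; identical seeds give bit-identical samples.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(24L, 64L, 64L),
                         tube_radius_px = 2.5,
                         tube_separation_px = 24,
                         centerline_wobble_amp = 2.5,
                         centerline_wobble_period = 36,
                         tube_intensity = 0.25,
                         background_intensity = 0.55,
                         fat_ring_intensity = 0.85,
                         noise_sigma = 0.05,
                         bbox_margin_px = 2L,
                         bbox_jitter_px = 1L,
                         seed = 1L) {
  spec <- list(shape = as.integer(shape),
               tube_radius_px = tube_radius_px,
               tube_separation_px = tube_separation_px,
               centerline_wobble_amp = centerline_wobble_amp,
               centerline_wobble_period = centerline_wobble_period,
               tube_intensity = tube_intensity,
               background_intensity = background_intensity,
               fat_ring_intensity = fat_ring_intensity,
               noise_sigma = noise_sigma,
               bbox_margin_px = as.integer(bbox_margin_px),
               bbox_jitter_px = as.integer(bbox_jitter_px),
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (length(spec$shape) != 3L || any(spec$shape < 1L)) {
    stopf("phantom_spec: shape must be 3 positive integers")
  }
  if (!(spec$tube_intensity < spec$background_intensity &&
        spec$background_intensity < spec$fat_ring_intensity)) {
    stopf("phantom_spec: intensities must satisfy tube < background < fat_ring")
  }
  if (spec$tube_radius_px <= 0) stopf("phantom_spec: tube_radius_px must be > 0")
  if (spec$bbox_margin_px < 0 || spec$bbox_jitter_px < 0) {
    stopf("phantom_spec: bbox margin/jitter must be >= 0")
  }
  # worst-case in-plane excursion of either tube, plus ring thickness
  reach <- spec$centerline_wobble_amp + spec$tube_radius_px + 1.5
  H <- spec$shape[2]; W <- spec$shape[3]
  cx <- W / 2 + c(-1, 1) * spec$tube_separation_px / 2
  if (H / 2 - reach < 1 || H / 2 + reach > H ||
      min(cx) - reach < 1 || max(cx) + reach > W) {
    stopf("phantom_spec: tubes (separation %g, wobble %g, radius %g) leave the %dx%d field of view",
          spec$tube_separation_px, spec$centerline_wobble_amp,
          spec$tube_radius_px, H, W)
  }
  invisible(spec)
}

# Minimum squared 3D distance from each in-plane pixel of slice z to a
# wobbling tube centerline (cx(t), cy(t), t), sampled densely in t.
tube_dist2_slice <- function(z, H, W, cx0, cy0, amp, period, phx, phy, radius) {
  reach <- radius + 1.5
  # include t = z itself so straight-tube sections are exact disks
  tt <- z + unique(c(0, seq(-reach, reach, by = 0.2)))
  cx <- cx0 + amp * sin(2 * pi * tt / period + phx)
  cy <- cy0 + amp * sin(2 * pi * tt / period + phy)
  rows <- seq_len(H); cols <- seq_len(W)
  d2 <- matrix(Inf, H, W)
  for (i in seq_along(tt)) {
    dz2 <- (z - tt[i])^2
    d2i <- outer((rows - cy[i])^2, (cols - cx[i])^2, `+`) + dz2
    d2 <- pmin(d2, d2i)
  }
  d2
}

#' Generate a synthetic two-tube phantom sample
#'
#' Rasterizes two sinusoidally wobbling tubes into a volume together
#' with the hidden ground-truth mask (voxels within `tube_radius_px` of
#' a centerline, measured in 3D so oblique sections widen correctly)
#' and the weak per-slice bounding-box mask: each tube's tight box,
#' dilated by `bbox_margin_px` on every side and shifted by a uniform
#' integer jitter in `[-bbox_jitter_px, bbox_jitter_px]`, then expanded
#' minimally so it still covers the tube (ground truth is always
#' contained in the weak mask).
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_sample`: list with `volume`
#'   ([volume()]), `gt` and `weak` ([mask_volume()]s), and `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  S <- spec$shape[1]; H <- spec$shape[2]; W <- spec$shape[3]
  set.seed(spec$seed)
  cy0 <- H / 2
  cx0 <- W / 2 + c(-1, 1) * spec$tube_separation_px / 2
  phx <- runif(2, 0, 2 * pi)
  phy <- runif(2, 0, 2 * pi)
  r <- spec$tube_radius_px
  img <- array(spec$background_intensity, c(S, H, W))
  gt <- array(0L, c(S, H, W))
  weak <- array(0L, c(S, H, W))
  jit <- function() if (spec$bbox_jitter_px > 0)
    sample(-spec$bbox_jitter_px:spec$bbox_jitter_px, 2, replace = TRUE) else c(0L, 0L)
  for (z in seq_len(S)) {
    for (tube in 1:2) {
      d2 <- tube_dist2_slice(z, H, W, cx0[tube], cy0,
                             spec$centerline_wobble_amp,
                             spec$centerline_wobble_period,
                             phx[tube], phy[tube], r)
      lumen <- d2 <= r^2
      ring <- d2 > r^2 & d2 <= (r + 1.5)^2
      sl <- img[z, , ]
      sl[ring] <- spec$fat_ring_intensity
      sl[lumen] <- spec$tube_intensity
      img[z, , ] <- sl
      g <- gt[z, , ]
      g[lumen] <- 1L
      gt[z, , ] <- g
      # weak box: tight box of this tube's section, dilated, jittered,
      # then re-covered so gt stays inside
      rr <- range(which(rowSums(lumen) > 0))
      cc <- range(which(colSums(lumen) > 0))
      m <- spec$bbox_margin_px
      j <- jit()
      r0 <- rr[1] - m + j[1]; r1 <- rr[2] + m + j[1]
      c0 <- cc[1] - m + j[2]; c1 <- cc[2] + m + j[2]
      r0 <- min(r0, rr[1]); r1 <- max(r1, rr[2])
      c0 <- min(c0, cc[1]); c1 <- max(c1, cc[2])
      r0 <- max(r0, 1L); r1 <- min(r1, H); c0 <- max(c0, 1L); c1 <- min(c1, W)
      wsl <- weak[z, , ]
      wsl[r0:r1, c0:c1] <- 1L
      weak[z, , ] <- wsl
    }
  }
  if (spec$noise_sigma > 0) {
    img <- img + array(rnorm(length(img), 0, spec$noise_sigma), dim(img))
  }
  img <- pmin(pmax(img, 0), 1)
  out <- list(volume = volume(img, spacing = c(1, 1, 1), dtype_tag = "unit-float"),
              gt = mask_volume(gt, provenance = "ground-truth"),
              weak = mask_volume(weak, provenance = "weak-bbox"),
              spec = spec)
  class(out) <- "phantom_sample"
  out
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("phantom_sample %s | tube r=%.2g px | contrast %.2g/%.2g/%.2g | seed %d\n",
              paste(x$spec$shape, collapse = "x"), x$spec$tube_radius_px,
              x$spec$tube_intensity, x$spec$background_intensity,
              x$spec$fat_ring_intensity, x$spec$seed))
  invisible(x)
}

#' Generate a dataset of phantom volumes with varying contrast
#'
#' Draws each volume's tube (lumen) intensity uniformly from
#' `contrast_range`, emulating the between-subject variation in carotid
#' contrast seen in real T1-weighted acquisitions, and derives each
#' volume's seed deterministically from the master seed.
#'
#' @param n_volumes number of volumes (>= 1).
#' @param spec_template a [phantom_spec()] supplying all other fields.
#' @param contrast_range `(lo, hi)` for the per-volume tube intensity.
#' @param seed master seed.
#' @return list of [generate_phantom()] samples.
#' @export
generate_dataset <- function(n_volumes, spec_template = phantom_spec(),
                             contrast_range = c(0.15, 0.35), seed = 1L) {
  if (n_volumes < 1) stopf("generate_dataset: n_volumes must be >= 1")
  if (length(contrast_range) != 2L || contrast_range[2] < contrast_range[1]) {
    stopf("generate_dataset: contrast_range must be (lo, hi) with hi >= lo")
  }
  lapply(seq_len(n_volumes), function(i) {
    set.seed(derive_seed(seed, 101L, i))
    ti <- runif(1, contrast_range[1], contrast_range[2])
    sp <- spec_template
    sp$tube_intensity <- ti
    sp$seed <- derive_seed(seed, 202L, i)
    validate_phantom_spec(sp)
    generate_phantom(sp)
  })
}

#' Write a phantom dataset to disk
#'
#' Emits, for each sample, NIfTI files `vol_<i>.nii.gz`,
#' `gt_<i>.nii.gz`, `weak_<i>.nii.gz` and a JSON manifest of the specs.
#'
#' @param samples list of `phantom_sample`s.
#' @param out_dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_phantom_dataset <- function(samples, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("write_phantom_dataset: cannot create %s", out_dir)
  manifest <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    write_volume(s$volume, file.path(out_dir, sprintf("vol_%03d.nii.gz", i)))
    write_volume(s$gt, file.path(out_dir, sprintf("gt_%03d.nii.gz", i)))
    write_volume(s$weak, file.path(out_dir, sprintf("weak_%03d.nii.gz", i)))
    manifest[[i]] <- c(list(index = i), unclass(s$spec))
  }
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
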