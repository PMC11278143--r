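#' Construct a volume
#'
#' A `volume` is a 3D scalar array plus voxel spacing. The package-wide
#' axis convention is: axis 1 indexes axial slices, axes 2 and 3 are the
#' in-plane (row, column) directions; `spacing` is `(sz, sy, sx)` in mm.
#'
#' @param data 3D numeric array ordered (slice, row, col).
#' @param spacing numeric length-3 voxel spacing in mm, `(sz, sy, sx)`.
#' @param dtype_tag one of `"uint16-like"`, `"uint8-like"`, `"unit-float"`.
#' @return an object of class `volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), dtype_tag = "unit-float") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("volume: data must be a 3D array, got %s dims",
          length(dim(data)) %||% 0L)
  }
  if (!is.numeric(data)) stopf("volume: data must be numeric")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("volume: spacing must be 3 positive numbers")
  }
  dtype_tag <- match.arg(dtype_tag, c("uint16-like", "uint8-like", "unit-float"))
  if (dtype_tag == "unit-float" &&
      (min(data) < -1e-9 || max(data) > 1 + 1e-9)) {
    stopf("volume: unit-float data must lie in [0, 1]")
  }
  structure(list(data = data, spacing = spacing, dtype_tag = dtype_tag),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("volume %s | spacing %s mm | %s | range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(x$spacing, collapse = "x"),
              x$dtype_tag, min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a mask volume
#'
#' A binary label volume aligned with a [volume()]. `provenance` records
#' how the labels arose: weak bounding boxes, self-training refinement,
#' or hidden ground truth.
#'
#' @param data 3D array with values in `{0, 1}`, ordered (slice, row, col).
#' @param provenance one of `"weak-bbox"`, `"refined"`, `"ground-truth"`.
#' @param spacing voxel spacing in mm.
#' @return an object of class `mask_volume`.
#' @export
mask_volume <- function(data, provenance = "weak-bbox", spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("mask_volume: data must be a 3D array")
  }
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1))) {
    stopf("mask_volume: values must be in {0, 1}; saw %s",
          paste(utils::head(setdiff(vals, c(0, 1)), 3), collapse = ", "))
  }
  provenance <- match.arg(provenance, c("weak-bbox", "refined", "ground-truth"))
  structure(list(data = data, provenance = provenance,
                 spacing = as.numeric(spacing)),
            class = "mask_volume")
}

#' Read a NIfTI-1 volume
#'
#' Reads a scalar 3D NIfTI file and normalises the axis order so that
#' axis 1 indexes axial slices (the NIfTI k axis) and spacing is
#' `(sz, sy, sx)`.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param mask if `TRUE`, return a [mask_volume()] (values checked binary).
#' @param provenance provenance tag used when `mask = TRUE`.
#' @return a [volume()] or [mask_volume()].
#' @export
read_volume <- function(path, mask = FALSE, provenance = "weak-bbox") {
  if (!file.exists(path)) stopf("read_volume: no such file: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("read_volume: %s is not a readable NIfTI file (%s)",
                                            path, conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L) {
    stopf("read_volume: %s has %d dimensions; expected a scalar 3D image",
          path, length(dim(arr)))
  }
  pd <- RNifti::pixdim(img)[1:3]
  # NIfTI stores (i, j, k) = (x, y, z); reorder to (slice, row, col) = (z, y, x)
  arr <- aperm(arr, c(3L, 2L, 1L))
  spacing <- as.numeric(pd[c(3L, 2L, 1L)])
  if (any(spacing <= 0)) spacing[spacing <= 0] <- 1
  if (mask) {
    mask_volume(arr, provenance = provenance, spacing = spacing)
  } else {
    rng <- range(arr)
    tag <- if (rng[1] >= 0 && rng[2] <= 1) "unit-float"
           else if (rng[2] <= 255) "uint8-like" else "uint16-like"
    volume(arr, spacing = spacing, dtype_tag = tag)
  }
}

#' Write a volume or mask volume to NIfTI-1
#'
#' Masks are written as uint8 with values in `{0, 1}`.
#'
#' @param v a [volume()] or [mask_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  arr <- aperm(v$data, c(3L, 2L, 1L))  # back to NIfTI (x, y, z)
  sp <- v$spacing[c(3L, 2L, 1L)]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  if (inherits(v, "mask_volume")) {
    img <- RNifti::asNifti(img, datatype = "uint8")
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume to isotropic spacing
#'
#' Resamples onto a `(target_mm)^3` grid; the output shape on each axis
#' is `round(extent_mm / target_mm)`. Images are interpolated
#' trilinearly; masks use nearest-neighbour so values stay binary.
#'
#' @param v a [volume()] or [mask_volume()].
#' @param target_mm target isotropic spacing in mm (default 1).
#' @param kind `"image"` or `"mask"`; defaults to `"mask"` for
#'   `mask_volume` inputs and `"image"` otherwise.
#' @return resampled object of the same class.
#' @export
resample_isotropic <- function(v, target_mm = 1.0,
                               kind = if (inherits(v, "mask_volume")) "mask" else "image") {
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0) {
    stopf("resample_isotropic: target_mm must be a positive number")
  }
  kind <- match.arg(kind, c("image", "mask"))
  sp <- v$spacing
  if (all(abs(sp - target_mm) < 1e-12)) return(v)
  old_dim <- dim(v$data)
  new_dim <- pmax(1L, as.integer(round_half_up(old_dim * sp / target_mm)))
  # output voxel i sits at physical (i-1)*target; input index = phys/sp + 1
  coords <- lapply(1:3, function(ax) {
    x <- ((seq_len(new_dim[ax]) - 1) * target_mm) / sp[ax] + 1
    pmin(pmax(x, 1), old_dim[ax])
  })
  if (kind == "mask") {
    idx <- lapply(coords, function(x) as.integer(round_half_up(x)))
    idx <- mapply(function(i, n) pmin(i, n), idx, old_dim, SIMPLIFY = FALSE)
    out <- v$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    lo <- lapply(1:3, function(ax) {
      l <- floor(coords[[ax]])
      pmax(pmin(l, old_dim[ax] - 1L), 1L)
    })
    w <- lapply(1:3, function(ax) coords[[ax]] - lo[[ax]])
    hi <- lapply(1:3, function(ax) pmin(lo[[ax]] + 1L, old_dim[ax]))
    out <- array(0, new_dim)
    for (a in 0:1) for (b in 0:1) for (c in 0:1) {
      i1 <- if (a == 0) lo[[1]] else hi[[1]]
      i2 <- if (b == 0) lo[[2]] else hi[[2]]
      i3 <- if (c == 0) lo[[3]] else hi[[3]]
      w1 <- if (a == 0) 1 - w[[1]] else w[[1]]
      w2 <- if (b == 0) 1 - w[[2]] else w[[2]]
      w3 <- if (c == 0) 1 - w[[3]] else w[[3]]
      wt <- outer(outer(w1, w2), w3)
      if (any(wt > 0)) {
        out <- out + v$data[i1, i2, i3, drop = FALSE] * wt
      }
    }
  }
  if (inherits(v, "mask_volume")) {
    mask_volume(out, provenance = v$provenance, spacing = rep(target_mm, 3))
  } else {
    vv <- v
    vv$data <- out
    vv$spacing <- rep(target_mm, 3)
    # interpolation can nudge unit-float values past 1 by rounding error
    if (vv$dtype_tag == "unit-float") vv$data <- pmin(pmax(vv$data, 0), 1)
    vv
  }
}

#' Quantize a volume to 8-bit integers
#'
#' Linearly rescales the per-volume intensity range `[min, max]` onto the
#' integers 0..255 (round half up). A constant volume maps to all zeros.
#' Parameter-free and preserves the volume's full dynamic range.
#'
#' @param v a [volume()].
#' @return a [volume()] with integer values 0..255, tagged `uint8-like`.
#' @export
quantize_to_8bit <- function(v) {
  rng <- range(v$data)
  d <- if (rng[2] - rng[1] <= 0) {
    array(0, dim(v$data))
  } else {
    round_half_up(255 * (v$data - rng[1]) / (rng[2] - rng[1]))
  }
  volume(d, spacing = v$spacing, dtype_tag = "uint8-like")
}

#' Normalize an 8-bit volume to the unit interval
#'
#' Divides each voxel by 255, giving values in `[0, 1]`.
#'
#' @param v an 8-bit quantized [volume()] (values in 0..255).
#' @return a unit-float [volume()].
#' @export
normalize_unit <- function(v) {
  if (min(v$data) < 0 || max(v$data) > 255) {
    stopf("normalize_unit: expected 8-bit values in [0, 255]; range is [%g, %g]",
          min(v$data), max(v$data))
  }
  volume(v$data / 255, spacing = v$spacing, dtype_tag = "unit-float")
}
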