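#' Stack an axial slice with its neighbours into a pseudo-RGB image
#'
#' Builds the 2.5D network input for slice `k`: channel R is the slice
#' below the target, G the target slice itself, B the slice above. At
#' the volume boundaries the missing neighbour is replaced by the edge
#' slice itself (edge replication), so no artificial zero channel is
#' introduced.
#'
#' @param v a unit-float [volume()].
#' @param k slice index, 1-based (`1 <= k <= S`).
#' @return an `H x W x 3` array with attributes `slice_index` and
#'   `channels = c("below", "target", "above")`.
#' @export
stack_neighbors <- function(v, k) {
  S <- dim(v$data)[1]
  if (k < 1 || k > S) stopf("stack_neighbors: slice index %d out of range 1..%d", k, S)
  lo <- max(k - 1L, 1L)
  hi <- min(k + 1L, S)
  H <- dim(v$data)[2]; W <- dim(v$data)[3]
  out <- array(0, c(H, W, 3L))
  out[, , 1] <- v$data[lo, , ]
  out[, , 2] <- v$data[k, , ]
  out[, , 3] <- v$data[hi, , ]
  attr(out, "slice_index") <- as.integer(k)
  attr(out, "channels") <- c("below", "target", "above")
  out
}

#' Construct a slice pair (image + mask + provenance)
#' @param image `H x W x 3` pseudo-RGB array.
#' @param mask `H x W` binary mask.
#' @param volume_id identifier of the source volume.
#' @param slice_index 1-based slice index within the volume.
#' @param provenance `"bbox"` or `"refined"`.
#' @return a `slice_pair` list.
#' @keywords internal
slice_pair <- function(image, mask, volume_id, slice_index, provenance = "bbox") {
  if (!identical(dim(image)[1:2], dim(mask)[1:2])) {
    stopf("slice_pair: image %s and mask %s shapes disagree (volume %s, slice %d)",
          paste(dim(image)[1:2], collapse = "x"),
          paste(dim(mask), collapse = "x"), volume_id, slice_index)
  }
  list(image = image, mask = mask, volume_id = volume_id,
       slice_index = as.integer(slice_index), provenance = provenance)
}

#' Build the training slice dataset from volumes and weak masks
#'
#' Emits one pseudo-RGB slice pair per axial slice whose weak mask is
#' non-empty; carotid-free slices are excluded from training. Volumes
#' must already be preprocessed to unit-float intensities.
#'
#' @param samples list of `list(volume = , mask = )` (a
#'   `phantom_sample` works directly, its `weak` mask being used).
#' @return list of `slice_pair`s, each carrying `volume_id` and
#'   `slice_index` for later re-assembly.
#' @export
build_slice_dataset <- function(samples) {
  out <- list()
  for (vi in seq_along(samples)) {
    s <- samples[[vi]]
    v <- s$volume
    m <- s$mask %||% s$weak
    if (is.null(v) || is.null(m)) stopf("build_slice_dataset: sample %d lacks volume or mask", vi)
    if (!identical(dim(v$data), dim(m$data))) {
      stopf("build_slice_dataset: volume %d shape %s but mask shape %s",
            vi, paste(dim(v$data), collapse = "x"), paste(dim(m$data), collapse = "x"))
    }
    vid <- s$volume_id %||% vi
    for (k in seq_len(dim(v$data)[1])) {
      msk <- m$data[k, , ]
      if (!any(msk != 0)) next
      out[[length(out) + 1L]] <- slice_pair(stack_neighbors(v, k), msk, vid, k)
    }
  }
  out
}
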