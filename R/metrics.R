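#' Intersection over Union (Jaccard index) of two binary masks
#'
#' `|a & b| / |a | b|`. Two empty masks are scored 1 by default: a correct
#' empty prediction should not be penalised. Set `empty = NA` to get `NA`
#' for the both-empty case instead (callers can then drop such items).
#'
#' @param a,b binary arrays of identical shape (0/1 or logical).
#' @param empty value returned when both masks are empty (default 1).
#' @return a scalar in `[0, 1]` (or `empty`).
#' @export
iou <- function(a, b, empty = 1) {
  check_same_shape(a, b)
  a <- a != 0; b <- b != 0
  u <- sum(a | b)
  if (u == 0) return(empty)
  sum(a & b) / u
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |a & b| / (|a| + |b|)`; related to [iou()] by
#' `dsc = 2 iou / (1 + iou)`. Both-empty convention as in [iou()].
#'
#' @inheritParams iou
#' @return a scalar in `[0, 1]` (or `empty`).
#' @export
dsc <- function(a, b, empty = 1) {
  check_same_shape(a, b)
  a <- a != 0; b <- b != 0
  s <- sum(a) + sum(b)
  if (s == 0) return(empty)
  2 * sum(a & b) / s
}

#' Evaluate a set of predictions against ground truth
#'
#' Computes per-item IoU and Dice plus their mean and population SD, the
#' aggregation used for validation monitoring and per-round reporting
#' (round, IoU mean +- SD, DSC mean +- SD).
#'
#' @param preds,gts lists of binary 2D masks of equal length.
#' @param ids optional item identifiers.
#' @param empty both-empty convention passed to [iou()]/[dsc()]; use
#'   `NA` to exclude both-empty items from the aggregates.
#' @return an `eval_report`: list with `per_item` (data.frame id/iou/dsc)
#'   and `iou_mean`, `iou_sd`, `dsc_mean`, `dsc_sd`.
#' @export
evaluate_masks <- function(preds, gts, ids = NULL, empty = 1) {
  if (length(preds) != length(gts)) {
    stopf("evaluate_masks: %d predictions vs %d ground-truth masks",
          length(preds), length(gts))
  }
  ids <- ids %||% seq_along(preds)
  ious <- mapply(function(p, g) iou(p, g, empty = empty), preds, gts)
  dscs <- mapply(function(p, g) dsc(p, g, empty = empty), preds, gts)
  per_item <- data.frame(id = ids, iou = ious, dsc = dscs,
                         row.names = NULL, stringsAsFactors = FALSE)
  ok_i <- ious[!is.na(ious)]
  ok_d <- dscs[!is.na(dscs)]
  out <- list(per_item = per_item,
              iou_mean = mean(ok_i), iou_sd = pop_sd(ok_i),
              dsc_mean = mean(ok_d), dsc_sd = pop_sd(ok_d))
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d items | IoU %.3f +- %.3f | DSC %.3f +- %.3f\n",
              nrow(x$per_item), x$iou_mean, x$iou_sd, x$dsc_mean, x$dsc_sd))
  invisible(x)
}

#' Write an evaluation report to CSV and JSON
#' @param report an `eval_report`.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) write.csv(report$per_item, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(iou_mean = report$iou_mean, iou_sd = report$iou_sd,
           dsc_mean = report$dsc_mean, dsc_sd = report$dsc_sd,
           n = nrow(report$per_item)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

check_same_shape <- function(a, b) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(da, db)) {
    stopf("mask shapes disagree: (%s) vs (%s)",
          paste(da, collapse = "x"), paste(db, collapse = "x"))
  }
  invisible(TRUE)
}
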