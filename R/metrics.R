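# Pixel-level segmentation metrics and classification accuracy.

#' Confusion counts between a predicted and a reference mask
#'
#' Per-pixel counts over the full raster; the prediction plays the role of
#' the algorithm segmentation (A), the reference that of the manual
#' segmentation (M).
#'
#' @param pred,ref 0/1 (or logical) matrices of identical dimensions.
#' @return Object of class `"confusion_counts"`: list with `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_counts <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) {
    stop_invalid("pred and ref masks must have identical dimensions")
  }
  p <- as.logical(pred)
  r <- as.logical(ref)
  structure(list(
    tp = sum(p & r), tn = sum(!p & !r),
    fp = sum(p & !r), fn = sum(!p & r)
  ), class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, Jaccard `|A intersect M| / |A union M| =
#' TP/(TP+FP+FN)`, and Dice `2 TP/(2 TP+FP+FN)`. A metric whose denominator
#' is zero is reported as `NA` (undefined), never coerced to 0 or 1.
#'
#' @param counts A `"confusion_counts"` object (or a mask pair via
#'   [confusion_counts()]).
#' @return Named list with `sensitivity`, `specificity`, `accuracy`,
#'   `jaccard`, `dice`.
#' @export
segmentation_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, list(
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    accuracy = safe(tp + tn, tp + tn + fp + fn),
    jaccard = safe(tp, tp + fp + fn),
    dice = safe(2 * tp, 2 * tp + fp + fn)
  ))
}

#' Dice coefficient of two masks
#'
#' Convenience wrapper: `segmentation_metrics(confusion_counts(a, b))$dice`.
#' @param pred,ref Binary masks.
#' @return Dice coefficient in [0, 1] (`NA` if both masks are empty).
#' @export
dice_coefficient <- function(pred, ref) {
  segmentation_metrics(confusion_counts(pred, ref))$dice
}

#' Overall classification accuracy
#'
#' The fraction of images whose predicted label matches the reference
#' label, with a percentage rendered to two decimals.
#'
#' @param pred_labels,ref_labels Equal-length non-empty vectors.
#' @return List with `n_correct`, `n_total`, `fraction`, `percent`
#'   (numeric, two-decimal rounding) and `printed`
#'   (e.g. `"402/436 (92.20%)"`).
#' @export
overall_classification_accuracy <- function(pred_labels, ref_labels) {
  if (length(pred_labels) == 0L || length(pred_labels) != length(ref_labels)) {
    stop_invalid("label vectors must be non-empty and of equal length")
  }
  n_correct <- sum(pred_labels == ref_labels)
  n_total <- length(ref_labels)
  frac <- n_correct / n_total
  pct <- round(100 * frac, 2)
  list(n_correct = n_correct, n_total = n_total, fraction = frac,
       percent = pct,
       printed = sprintf("%d/%d (%.2f%%)", n_correct, n_total, pct))
}
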