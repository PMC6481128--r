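# Evaluation metrics. The method's printed formulas are kept verbatim as
# the headline output, with the standard definitions computed alongside:
# the printed Dice (TP+TN)/(TP+TN+FP+FN) is pixel accuracy, the printed
# Sensitivity TP/(TP+FP) is precision, and the printed Specificity
# FN/(TN+FN) is nonstandard; Recall TP/(TP+FN) coincides in both
# families. Both are reported so results are comparable either way.

#' Pixelwise confusion counts between two masks
#'
#' @param pred predicted [BinaryMask-class].
#' @param truth ground-truth [BinaryMask-class], same shape.
#' @param roi optional [BinaryMask-class] restricting evaluation; default
#'   is the whole image.
#' @return a [ConfusionCounts-class] with TP = pred & truth,
#'   TN = !pred & !truth, FP = pred & !truth, FN = !pred & truth.
#' @export
confusionCounts <- function(pred, truth, roi = NULL) {
  p <- asMaskMatrix(pred); t <- asMaskMatrix(truth)
  if (!identical(dim(p), dim(t)))
    stop("mask shapes differ: ", paste(dim(p), collapse = "x"), " vs ",
         paste(dim(t), collapse = "x"))
  keep <- if (is.null(roi)) TRUE else {
    r <- asMaskMatrix(roi)
    if (!identical(dim(r), dim(p))) stop("roi shape differs from masks")
    r
  }
  p <- p[keep]; t <- t[keep]
  new("ConfusionCounts",
      TP = sum(p & t), TN = sum(!p & !t), FP = sum(p & !t), FN = sum(!p & t))
}

ratioOrNaN <- function(num, den, what) {
  if (den == 0) {
    warning("undefined ", what, ": zero denominator", call. = FALSE)
    return(NaN)
  }
  num / den
}

#' Overlap metrics from confusion counts
#'
#' Computes Dice, Sensitivity, Specificity and Recall under the printed
#' formulas (`paper`) and under the standard definitions (`standard`);
#' see [MetricsReport-class]. Ratios with zero denominators are NaN with
#' a warning, so batch evaluation never aborts.
#'
#' @param counts a [ConfusionCounts-class], or a predicted mask (then
#'   `truth` must be given and counts are tallied first).
#' @param truth optional ground-truth mask when `counts` is a mask.
#' @param roi optional evaluation region, see [confusionCounts()].
#' @return a [MetricsReport-class].
#' @examples
#' cc <- new("ConfusionCounts", TP = 50, TN = 40, FP = 5, FN = 5)
#' segMetrics(cc)
#' @export
segMetrics <- function(counts, truth = NULL, roi = NULL) {
  if (!is(counts, "ConfusionCounts"))
    counts <- confusionCounts(counts, truth, roi)
  TP <- counts@TP; TN <- counts@TN; FP <- counts@FP; FN <- counts@FN
  if (TP + TN + FP + FN == 0) stop("all confusion counts are zero")
  paper <- c(
    dice        = ratioOrNaN(TP + TN, TP + TN + FP + FN, "paper dice"),
    sensitivity = ratioOrNaN(TP, TP + FP, "paper sensitivity"),
    specificity = ratioOrNaN(FN, TN + FN, "paper specificity"),
    recall      = ratioOrNaN(TP, TP + FN, "recall"))
  standard <- c(
    dice        = ratioOrNaN(2 * TP, 2 * TP + FP + FN, "standard dice"),
    sensitivity = ratioOrNaN(TP, TP + FN, "standard sensitivity"),
    specificity = ratioOrNaN(TN, TN + FP, "standard specificity"),
    recall      = ratioOrNaN(TP, TP + FN, "recall"))
  new("MetricsReport", paper = paper, standard = standard, counts = counts)
}

#' Standard Dice coefficient between two masks
#'
#' Convenience wrapper: `2 TP / (2 TP + FP + FN)`.
#'
#' @inheritParams confusionCounts
#' @return the standard Dice coefficient.
#' @export
diceCoefficient <- function(pred, truth, roi = NULL) {
  suppressWarnings(segMetrics(pred, truth, roi)@standard[["dice"]])
}
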