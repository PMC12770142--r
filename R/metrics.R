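#' Confusion counts and classification metrics
#'
#' `confusion()` tabulates TP/FP/TN/FN from binary labels and predictions.
#' `classification_metrics()` computes the evaluation panel: AUC (midrank
#' Mann-Whitney over the continuous scores), accuracy, sensitivity,
#' specificity, G-mean (`sqrt(sensitivity * specificity)`) and F1
#' (`2TP / (2TP + FP + FN)`). With balanced classes, accuracy equals
#' `(sensitivity + specificity) / 2`.
#'
#' @param labels binary ground truth (0/1, logical, or benign/malignant).
#' @param predicted binary predictions.
#' @return `confusion()` returns a named vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(labels, predicted) {
  y <- as_binary_label(labels)
  p <- as.numeric(predicted)
  if (length(y) != length(p)) stop("labels and predictions differ in length")
  c(TP = sum(y == 1 & p == 1), FP = sum(y == 0 & p == 1),
    TN = sum(y == 0 & p == 0), FN = sum(y == 1 & p == 0))
}

#' @param scores continuous scores (e.g. predicted probabilities) used for
#'   the AUC; if `NULL` the AUC is `NA`.
#' @param threshold decision threshold, boundary counted positive.
#' @rdname confusion
#' @return `classification_metrics()` returns a one-row data.frame with
#'   columns `auc`, `accuracy`, `sensitivity`, `specificity`, `gmean`, `f1`.
#' @export
classification_metrics <- function(labels, scores = NULL,
                                   predicted = NULL, threshold = 0.5) {
  y <- as_binary_label(labels)
  if (is.null(predicted)) {
    if (is.null(scores)) stop("provide scores and/or predictions")
    predicted <- as.integer(scores >= threshold)
  }
  cc <- confusion(y, predicted)
  sens <- unname(cc["TP"] / (cc["TP"] + cc["FN"]))
  spec <- unname(cc["TN"] / (cc["TN"] + cc["FP"]))
  data.frame(
    auc = if (is.null(scores)) NA_real_ else auc_score(y, scores),
    accuracy = unname((cc["TP"] + cc["TN"]) / sum(cc)),
    sensitivity = sens,
    specificity = spec,
    gmean = metric_gmean(sens, spec),
    f1 = unname(2 * cc["TP"] / (2 * cc["TP"] + cc["FP"] + cc["FN"]))
  )
}

#' Area under the ROC curve (midrank Mann-Whitney)
#'
#' Equivalent to counting concordant positive-negative score pairs with
#' ties worth one half.
#'
#' @param labels binary ground truth containing both classes.
#' @param scores continuous scores.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(labels, scores) {
  y <- as_binary_label(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC is undefined for single-class labels")
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Metric identities on sensitivity/specificity pairs
#'
#' The geometric mean of sensitivity and specificity, and the accuracy of a
#' class-balanced cohort, as functions of (sensitivity, specificity). These
#' identities let reported metric triples be checked for internal
#' consistency.
#'
#' @param sensitivity,specificity values in \[0, 1\].
#' @return numeric value.
#' @export
#' @examples
#' metric_gmean(0.583, 0.658)             # 0.619 to 3 dp
#' metric_balanced_accuracy(0.95, 0.35)   # 0.650
metric_gmean <- function(sensitivity, specificity) {
  sqrt(sensitivity * specificity)
}

#' @rdname metric_gmean
#' @export
metric_balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}
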