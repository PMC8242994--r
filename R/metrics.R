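# Evaluation metrics for imbalanced binary classification: the confusion
# matrix, precision/recall/accuracy/F1/MCC, and the ranking metrics AUC and
# AUPRC. All implemented natively and pinned to independent oracles in the
# test suite.

check_binary <- function(x, name) {
  if (!is.numeric(x) && !is.logical(x)) {
    opcnn_stop(sprintf("`%s` must be numeric 0/1", name), "data_error")
  }
  x <- as.numeric(x)
  if (!all(x %in% c(0, 1))) {
    opcnn_stop(sprintf("`%s` must contain only 0 and 1", name), "data_error")
  }
  x
}

#' Confusion counts of a binary prediction
#'
#' @param y_true,y_pred Binary (0/1) vectors of equal length; 1 is the
#'   positive class (approved drugs), 0 the negative class (failed drugs).
#' @return A list of class `"confusion_counts"` with integer fields
#'   `TP`, `FN`, `TN`, `FP`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- check_binary(y_true, "y_true")
  y_pred <- check_binary(y_pred, "y_pred")
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    opcnn_stop("`y_true` and `y_pred` must have equal length >= 1",
               "dimension_error")
  }
  structure(list(
    TP = sum(y_true == 1 & y_pred == 1),
    FN = sum(y_true == 1 & y_pred == 0),
    TN = sum(y_true == 0 & y_pred == 0),
    FP = sum(y_true == 0 & y_pred == 1)
  ), class = "confusion_counts")
}

#' Threshold metrics from confusion counts
#'
#' Computes precision, recall, accuracy, F1-score, and the Matthews
#' correlation coefficient:
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}}}
#' Degenerate denominators follow the standard conventions: precision or
#' recall with an empty denominator is 0, F1 with `PR + RE = 0` is 0, and
#' MCC with any zero factor under the square root is 0 (the prediction then
#' carries no information about the missing category).
#'
#' @param cc A [confusion()] object, or a list with fields TP, FN, TN, FP.
#' @return Named numeric vector with elements `PR`, `RE`, `ACC`, `F1`, `MCC`.
#' @export
compute_metrics <- function(cc) {
  tp <- as.numeric(cc$TP); fn <- as.numeric(cc$FN)
  tn <- as.numeric(cc$TN); fp <- as.numeric(cc$FP)
  if (any(c(tp, fn, tn, fp) < 0) || tp + fn + tn + fp <= 0) {
    opcnn_stop("confusion counts must be non-negative with positive total",
               "data_error")
  }
  n <- tp + fn + tn + fp
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  re <- if (tp + fn > 0) tp / (tp + fn) else 0
  acc <- (tp + tn) / n
  f1 <- if (pr + re > 0) 2 * pr * re / (pr + re) else 0
  denom <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  c(PR = pr, RE = re, ACC = acc, F1 = f1, MCC = mcc)
}

#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney rank statistic: the probability that a
#' random positive outscores a random negative, counting ties as 1/2
#' (midranks).
#'
#' @param scores Numeric score vector (higher = more positive).
#' @param y_true Binary labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, y_true) {
  y_true <- check_binary(y_true, "y_true")
  if (length(scores) != length(y_true)) {
    opcnn_stop("`scores` and `y_true` must have equal length",
               "dimension_error")
  }
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) {
    opcnn_stop("roc_auc is undefined when only one class is present",
               "undefined_metric_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step integration over descending score thresholds (average-precision
#' style): tied scores are grouped at a single threshold and each threshold
#' contributes `(recall gain) x precision`. Trapezoidal interpolation is
#' deliberately not used, as it overestimates precision-recall areas.
#'
#' @inheritParams roc_auc
#' @return AUPRC in \[0, 1\]; equals the prevalence for constant scores.
#' @export
pr_auc <- function(scores, y_true) {
  y_true <- check_binary(y_true, "y_true")
  if (length(scores) != length(y_true)) {
    opcnn_stop("`scores` and `y_true` must have equal length",
               "dimension_error")
  }
  n_pos <- sum(y_true == 1)
  if (n_pos == 0) {
    opcnn_stop("pr_auc is undefined without positive samples",
               "undefined_metric_error")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  yy <- y_true[o]
  last_of_group <- !duplicated(s, fromLast = TRUE) # threshold = each unique score
  tp <- cumsum(yy)[last_of_group]
  np <- seq_along(yy)[last_of_group]               # predicted-positive count
  prec <- tp / np
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Full metric set from scores
#'
#' Thresholds the scores at `threshold` (default 0.5, the natural sigmoid
#' threshold) for the confusion-based metrics and adds the ranking metrics
#' AUC and AUPRC. With `allow_undefined = TRUE`, ranking metrics that are
#' undefined for the given labels are returned as `NA` instead of erroring
#' (used by the cross-validation harness to drop, not impute, such repeats).
#'
#' @param scores Numeric scores in any range (probabilities expected).
#' @param y_true Binary labels.
#' @param threshold Decision threshold for hard labels.
#' @param allow_undefined Return NA instead of erroring on degenerate labels.
#' @return Named numeric vector `PR, RE, ACC, F1, MCC, AUC, AUPRC`.
#' @export
metric_set <- function(scores, y_true, threshold = 0.5,
                       allow_undefined = FALSE) {
  y_pred <- as.numeric(scores >= threshold)
  base <- compute_metrics(confusion(y_true, y_pred))
  rank_metric <- function(f) {
    if (allow_undefined) {
      tryCatch(f(scores, y_true),
               undefined_metric_error = function(e) NA_real_)
    } else {
      f(scores, y_true)
    }
  }
  c(base, AUC = rank_metric(roc_auc), AUPRC = rank_metric(pr_auc))
}

# Column labels used when serialising metric tables (report headers).
metric_labels <- c(PR = "Precision", RE = "Recall", ACC = "ACC",
                   F1 = "F1-score", MCC = "MCC", AUC = "AUC",
                   AUPRC = "AUPRC")

#' ROC and precision-recall curve coordinates
#'
#' One row per decision threshold (each unique score, descending), with the
#' true/false positive rates and precision/recall at that threshold —
#' ready for external plotting or CSV export.
#'
#' @inheritParams roc_auc
#' @return A data.frame with columns `threshold`, `tpr`, `fpr`,
#'   `precision`, `recall`.
#' @export
curve_coordinates <- function(scores, y_true) {
  y_true <- check_binary(y_true, "y_true")
  if (length(scores) != length(y_true)) {
    opcnn_stop("`scores` and `y_true` must have equal length",
               "dimension_error")
  }
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    opcnn_stop("curve coordinates need both classes", "undefined_metric_error")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  yy <- y_true[o]
  last <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(yy)[last]
  np <- seq_along(yy)[last]
  fp <- np - tp
  data.frame(threshold = s[last], tpr = tp / n_pos, fpr = fp / n_neg,
             precision = tp / np, recall = tp / n_pos)
}
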