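#' Classification metrics for a binary prediction score
#'
#' Computes the standard report for girl/boy prediction: balanced accuracy
#' (mean of the per-class recalls), true positive rate, true negative rate,
#' false positive rate, tie-aware AUC, and the confusion counts. The positive
#' class is girls (label 1). Scores are binarized at `threshold`, with ties at
#' the threshold assigned to class 0 (boy) so the rule is deterministic.
#'
#' @param scores Numeric prediction scores (probability of girl).
#' @param labels Binary labels (girl = 1, boy = 0).
#' @param threshold Binarization threshold (default 0.5).
#' @return Object of class `metrics_report`: list with `balanced_accuracy`,
#'   `tpr`, `tnr`, `fpr`, `auc`, `accuracy`, and `confusion` (tp, fn, tn, fp).
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("compute_metrics: metrics undefined for single-class labels")
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  tpr <- tp / (tp + fn)
  tnr <- tn / (tn + fp)
  structure(list(
    balanced_accuracy = (tpr + tnr) / 2,
    tpr = tpr, tnr = tnr, fpr = 1 - tnr,
    auc = auc_mann_whitney(scores, labels),
    accuracy = mean(pred == labels),
    confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
    threshold = threshold
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Classification metrics (girls = 1, boys = 0)\n")
  cat(sprintf("  balanced accuracy: %.3f\n", x$balanced_accuracy))
  cat(sprintf("  TPR %.3f  TNR %.3f  FPR %.3f  AUC %.3f\n",
              x$tpr, x$tnr, x$fpr, x$auc))
  cat(sprintf("  confusion: tp=%d fn=%d tn=%d fp=%d\n",
              x$confusion["tp"], x$confusion["fn"],
              x$confusion["tn"], x$confusion["fp"]))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(balanced_accuracy = x$balanced_accuracy, tpr = x$tpr,
             tnr = x$tnr, fpr = x$fpr, auc = x$auc, accuracy = x$accuracy)
}
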