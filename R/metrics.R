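# Confusion matrices and classification metrics.

#' Confusion matrix from true and predicted labels
#'
#' @param truth,pred Integer class labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @return An `n_classes x n_classes` integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(truth, pred, n_classes) {
  if (length(truth) != length(pred)) stop("length mismatch", call. = FALSE)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  cm
}

#' Accuracy, per-class precision/recall/F1 and macro F1
#'
#' Per class (one-vs-rest): precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2 * precision * recall / (precision + recall); zero denominators
#' yield 0 with a warning. Accuracy is the multiclass trace ratio. The
#' headline F1 is the unweighted (macro) mean; a count-weighted average is
#' also reported.
#'
#' @param cm Square confusion-matrix counts (rows = true).
#' @return List with `accuracy`, `per_class` data frame, `macro_f1`,
#'   `weighted_f1`, `n`.
#' @export
compute_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square",
                                 call. = FALSE)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  k <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) warning("zero denominator in ", what, "; reported as 0",
                               call. = FALSE)
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  support <- rowSums(cm)
  list(accuracy = sum(tp) / n,
       per_class = data.frame(class = seq_len(k), precision = precision,
                              recall = recall, f1 = f1, support = support),
       macro_f1 = mean(f1),
       weighted_f1 = sum(f1 * support) / n,
       n = n)
}
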