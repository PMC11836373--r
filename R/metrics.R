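# Confusion-matrix metrics: accuracy, macro-averaged precision/recall/F1
# and minority-class accuracy (recall of the smallest-support class).

#' Confusion matrix
#'
#' Rows index the true class, columns the predicted class.
#'
#' @param y_true,y_pred integer labels in `1..C`.
#' @param n_classes number of classes `C`.
#' @return C x C integer matrix of counts.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stopf("y_true and y_pred lengths differ")
  if (length(y_true) &&
      (min(c(y_true, y_pred)) < 1L || max(c(y_true, y_pred)) > n_classes))
    stopf("labels must lie in 1..%d", n_classes)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true))
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  cm
}

#' Macro-averaged metrics from a confusion matrix
#'
#' Per class: precision = diagonal / column sum, recall = diagonal / row
#' sum (0 when the denominator is 0), F1 = harmonic mean (0 when both are
#' 0). Macro values are unweighted class means; accuracy is trace / total.
#' Classes absent from the truth contribute 0 recall and are flagged.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @return list with `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, `per_class` (data frame with precision/recall/F1/support)
#'   and `absent_classes` (indices with zero support).
#' @export
macro_metrics <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stopf("confusion matrix is empty")
  C <- nrow(cm)
  diagv <- diag(cm)
  rs <- rowSums(cm); cs <- colSums(cm)
  recall <- ifelse(rs > 0, diagv / rs, 0)
  precision <- ifelse(cs > 0, diagv / cs, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(accuracy = sum(diagv) / total,
       macro_precision = mean(precision),
       macro_recall = mean(recall),
       macro_f1 = mean(f1),
       per_class = data.frame(class = seq_len(C), precision = precision,
                              recall = recall, f1 = f1, support = rs),
       absent_classes = which(rs == 0))
}

#' Minority-class accuracy
#'
#' Recall of the class with the smallest support; ties resolved in favour
#' of the lowest class index.
#'
#' @param cm confusion matrix.
#' @param support per-class supports (must sum to `sum(cm)`); defaults to
#'   the confusion-matrix row sums, but callers should pass the original
#'   pre-resampling supports when the evaluation set was rebalanced.
#' @return recall of the minority class.
#' @export
minority_class_accuracy <- function(cm, support = rowSums(cm)) {
  if (length(support) != nrow(cm)) stopf("one support per class required")
  m <- which.min(support)  # ties -> lowest index
  rs <- sum(cm[m, ])
  if (rs == 0) return(0)
  cm[m, m] / rs
}

#' Full metrics report
#'
#' @inheritParams minority_class_accuracy
#' @param class_names optional class names for the per-class table.
#' @return a `metrics_report` list (accuracy, macro precision/recall/F1,
#'   minority-class accuracy, per-class table).
#' @export
metrics_report <- function(cm, support = rowSums(cm), class_names = NULL) {
  mm <- macro_metrics(cm)
  if (!is.null(class_names)) mm$per_class$class <- class_names
  structure(c(mm, list(minority_class_accuracy =
                         minority_class_accuracy(cm, support),
                       confusion = cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy                %.4f\n", x$accuracy))
  cat(sprintf("precision (macro avg.)  %.4f\n", x$macro_precision))
  cat(sprintf("recall (macro avg.)     %.4f\n", x$macro_recall))
  cat(sprintf("F1-score (macro avg.)   %.4f\n", x$macro_f1))
  cat(sprintf("minority class accuracy %.4f\n", x$minority_class_accuracy))
  invisible(x)
}

#' Write a metrics report as CSV
#'
#' One `metric,value` row per summary metric, matching the report print
#' order.
#'
#' @param report a [metrics_report()]. @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  df <- data.frame(
    metric = c("accuracy", "precision_macro", "recall_macro", "f1_macro",
               "minority_class_accuracy"),
    value = c(report$accuracy, report$macro_precision, report$macro_recall,
              report$macro_f1, report$minority_class_accuracy))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
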