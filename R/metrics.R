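#' Threshold classification metrics
#'
#' Hard labels are taken as `1{y_prob >= threshold}` and accuracy,
#' precision, recall and F1 are computed from the confusion counts. With no
#' predicted positives, precision is reported as 0 and flagged; likewise
#' recall with no true positives in the data. F1 is 0 when precision and
#' recall are both 0.
#'
#' @param y_true Binary label vector.
#' @param y_prob Probability vector in `[0, 1]`.
#' @param threshold Label cut-off, default 0.5 (`>=` maps to class 1).
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `f1`,
#'   `threshold`, and degenerate-case flags `precision_degenerate`,
#'   `recall_degenerate`.
#' @examples
#' classification_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.1))
#' @export
classification_metrics <- function(y_true, y_prob, threshold = 0.5) {
  if (length(y_true) == 0) abort("Empty input.")
  if (length(y_true) != length(y_prob)) abort("Length mismatch.")
  y_hat <- as.integer(y_prob >= threshold)
  tp <- sum(y_true == 1 & y_hat == 1)
  fp <- sum(y_true == 0 & y_hat == 1)
  fn <- sum(y_true == 1 & y_hat == 0)
  tn <- sum(y_true == 0 & y_hat == 0)
  no_pred_pos <- (tp + fp) == 0
  no_true_pos <- (tp + fn) == 0
  precision <- if (no_pred_pos) 0 else tp / (tp + fp)
  recall <- if (no_true_pos) 0 else tp / (tp + fn)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(
    accuracy = (tp + tn) / length(y_true),
    precision = precision,
    recall = recall,
    f1 = f1,
    threshold = threshold,
    precision_degenerate = no_pred_pos,
    recall_degenerate = no_true_pos
  )
}

#' ROC curve and trapezoidal AUC
#'
#' Builds the ROC curve by sweeping a threshold over every distinct score in
#' descending order (tied scores share one step), anchored at (0, 0) and
#' ending at (1, 1), and integrates it with the trapezoidal rule:
#' `AUC = sum_i (TPR_i + TPR_{i+1}) * (FPR_{i+1} - FPR_i) / 2`. This equals
#' the probability that a random positive outscores a random negative, ties
#' counted one half.
#'
#' @param y_true Binary label vector containing both classes.
#' @param y_prob Score/probability vector.
#' @return List with `roc_points` — a tibble of (`threshold`, `fpr`, `tpr`)
#'   with leading anchor row — and `auc`.
#' @export
roc_auc <- function(y_true, y_prob) {
  if (length(y_true) != length(y_prob)) abort("Length mismatch.")
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC undefined: both classes must be present.")
  }
  ord <- order(y_prob, decreasing = TRUE)
  y_sorted <- y_true[ord]
  p_sorted <- y_prob[ord]
  keep <- !duplicated(p_sorted, fromLast = TRUE)  # last index of each tie run
  tpr <- c(0, cumsum(y_sorted == 1)[keep] / n_pos)
  fpr <- c(0, cumsum(y_sorted == 0)[keep] / n_neg)
  thr <- c(Inf, p_sorted[keep])
  auc <- sum((tpr[-1] + tpr[-length(tpr)]) * diff(fpr)) / 2
  list(
    roc_points = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr),
    auc = auc
  )
}

#' Full metrics report for one fitted ensemble
#'
#' Bundles the thresholded classification metrics with the ROC curve and
#' trapezoidal AUC for one set of labels and ensemble probabilities.
#'
#' @param y_true Binary label vector (both classes present for the AUC).
#' @param y_prob Probability vector.
#' @param threshold Label cut-off, default 0.5.
#' @return A `metrics_report`: list with the metrics tibble (now including
#'   `auc`), `roc_points`, and `threshold`.
#' @export
metrics_report <- function(y_true, y_prob, threshold = 0.5) {
  cm <- classification_metrics(y_true, y_prob, threshold)
  roc <- roc_auc(y_true, y_prob)
  cm$auc <- roc$auc
  structure(
    list(metrics = dplyr::relocate(cm, "auc", .after = "f1"),
         roc_points = roc$roc_points,
         threshold = threshold),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<metrics_report> acc %.4f | precision %.4f | recall %.4f | F1 %.4f | AUC %.4f (threshold %.2f)\n",
    m$accuracy, m$precision, m$recall, m$f1, m$auc, x$threshold
  ))
  invisible(x)
}

#' @rdname metrics_report
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$metrics

#' Plot the ROC curve of a metrics report
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.4f)", object$metrics$auc)
    ) +
    ggplot2::theme_minimal()
}
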