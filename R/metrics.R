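## Benchmarks: accuracy at the 0.5 threshold, precision / recall / F1 with
## binding as the positive class, and AUC-ROC by the rank (Mann-Whitney)
## formulation with ties averaged.

#' Classification benchmarks for binding-probability scores
#'
#' @param scores Per-sample binding probabilities (or any monotone score).
#' @param labels Binary labels (1 binding, 0 non-binding).
#' @return List of class `metrics_report`: `accuracy`, `auc_roc`,
#'   `f_score`, `precision`, `recall`, `n_samples`. With single-class
#'   labels the AUC is undefined and returned as `NA` with a warning;
#'   precision (and F) are 0 when no sample is predicted positive.
#' @export
classification_metrics <- function(scores, labels) {
  abort_if(length(scores) != length(labels),
           "scores (%d) and labels (%d) differ in length",
           length(scores), length(labels))
  abort_if(!all(labels %in% c(0, 1)), "labels must be binary 0/1")
  n <- length(labels)
  abort_if(n == 0L, "empty input")
  pred <- as.integer(scores > 0.5)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  accuracy <- mean(pred == labels)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f_score <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  n1 <- sum(labels == 1); n0 <- n - n1
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined for single-class labels; returning NA")
    auc <- NA_real_
  } else {
    r <- rank(scores)                      # ties averaged
    auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(list(accuracy = accuracy, auc_roc = auc, f_score = f_score,
                 precision = precision, recall = recall, n_samples = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "n = %d  accuracy %.3f  AUC-ROC %s  F %.3f  precision %.3f  recall %.3f\n",
    x$n_samples, x$accuracy,
    if (is.na(x$auc_roc)) "NA" else sprintf("%.3f", x$auc_roc),
    x$f_score, x$precision, x$recall))
  invisible(x)
}

#' ROC curve points
#'
#' Sweeps the score thresholds from high to low (tied scores grouped) and
#' returns the (FPR, TPR) path from (0, 0) to (1, 1); its trapezoidal area
#' equals the rank-based AUC of [classification_metrics()].
#'
#' @param scores Per-sample binding probabilities.
#' @param labels Binary labels.
#' @return data.frame with columns `fpr` and `tpr`, both monotone
#'   non-decreasing.
#' @export
roc_curve <- function(scores, labels) {
  abort_if(length(scores) != length(labels),
           "scores and labels differ in length")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  abort_if(n1 == 0L || n0 == 0L,
           "ROC undefined: need both classes among the labels")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp_last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied group
  tp <- cumsum(y)[grp_last]
  fpos <- cumsum(1 - y)[grp_last]
  data.frame(fpr = c(0, fpos / n0), tpr = c(0, tp / n1))
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc data.frame from [roc_curve()].
#' @return Scalar area.
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
}

#' Write a metrics report as JSON and/or one-row TSV
#'
#' The TSV column order follows the benchmark tables: accuracy, AUC-ROC,
#' F-score, precision, recall.
#'
#' @param report A `metrics_report`.
#' @param json_path,tsv_path Output paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_metrics <- function(report, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report), json_path, digits = NA,
                         auto_unbox = TRUE)
  if (!is.null(tsv_path)) {
    df <- data.frame(accuracy = report$accuracy, auc_roc = report$auc_roc,
                     f_score = report$f_score, precision = report$precision,
                     recall = report$recall, n = report$n_samples)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report)
}
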