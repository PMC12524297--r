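#' Classification metrics from a confusion matrix
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), Precision = TP/(TP+FP),
#' Recall = TP/(TP+FN), F1 = 2PR/(P+R). A quantity with a zero denominator
#' (no actual positives, or no predicted positives) is reported as NA and
#' named in the \code{undefined} field rather than silently set to 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @param auc Optional AUC to carry into the report.
#' @return Object of class \code{hcn_metrics}: accuracy, precision, recall,
#'   f1, auc, confusion (tp/tn/fp/fn), n, undefined.
#' @examples
#' m <- metrics_from_confusion(tp = 225, tn = 208, fp = 25, fn = 10)
#' m$accuracy  # 433/468
#' @export
metrics_from_confusion <- function(tp, tn, fp, fn, auc = NA_real_) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stop("empty confusion matrix")
  undefined <- character(0)
  accuracy <- (tp + tn) / n
  if (tp + fp > 0) precision <- tp / (tp + fp) else {
    precision <- NA_real_; undefined <- c(undefined, "precision")
  }
  if (tp + fn > 0) recall <- tp / (tp + fn) else {
    recall <- NA_real_; undefined <- c(undefined, "recall")
  }
  if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    f1 <- 2 * precision * recall / (precision + recall)
  } else {
    f1 <- NA_real_; undefined <- c(undefined, "f1")
  }
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1, auc = auc,
                 confusion = as.list(counts), n = as.integer(n),
                 undefined = undefined),
            class = "hcn_metrics")
}

#' Classification metrics from probabilities
#'
#' Thresholds the probabilities (class 1 iff probability >= threshold),
#' counts the confusion matrix, applies the standard metric formulas and
#' computes AUC by the Mann-Whitney rank statistic with midrank handling of
#' ties (a constant score therefore gives AUC 0.5). If only one true class
#' is present the rank AUC is undefined and reported as NA with a flag.
#'
#' @param y_true Binary labels.
#' @param y_prob Predicted probabilities (same length).
#' @param threshold Decision threshold (default 0.5).
#' @return An \code{hcn_metrics} (see \code{\link{metrics_from_confusion}}).
#' @export
compute_metrics <- function(y_true, y_prob, threshold = 0.5) {
  y_true <- as.numeric(y_true)
  y_prob <- as.numeric(y_prob)
  if (length(y_true) != length(y_prob)) stop("length mismatch")
  if (length(y_true) == 0L) stop("no samples to evaluate")
  if (!all(y_true %in% c(0, 1))) stop("y_true must be 0/1")
  y_hat <- as.integer(y_prob >= threshold)
  m <- metrics_from_confusion(
    tp = sum(y_hat == 1 & y_true == 1),
    tn = sum(y_hat == 0 & y_true == 0),
    fp = sum(y_hat == 1 & y_true == 0),
    fn = sum(y_hat == 0 & y_true == 1))
  m$auc <- auc_rank(y_true, y_prob)
  if (is.na(m$auc)) m$undefined <- c(m$undefined, "auc")
  m
}

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' @param y_true Binary labels.
#' @param y_prob Scores; ties are handled by midranks.
#' @return AUC in [0, 1], or NA if a class is absent.
#' @export
auc_rank <- function(y_true, y_prob) {
  pos <- y_true == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(y_prob)  # midranks for ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.hcn_metrics <- function(x, ...) {
  cat(sprintf(
    "<hcn_metrics> n=%d  acc=%.4f  prec=%s  rec=%s  f1=%s  auc=%s\n",
    x$n, x$accuracy, fmt_or_na(x$precision), fmt_or_na(x$recall),
    fmt_or_na(x$f1), fmt_or_na(x$auc)))
  cat(sprintf("  confusion: TP=%d TN=%d FP=%d FN=%d\n",
              x$confusion$tp, x$confusion$tn, x$confusion$fp, x$confusion$fn))
  if (length(x$undefined)) {
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)

metric_names <- c("accuracy", "precision", "recall", "f1", "auc")

metrics_row <- function(m) {
  as.data.frame(m[metric_names])
}

# mean +/- SD aggregation; SD over a single run is reported as 0
mean_sd <- function(values) {
  c(mean = mean(values),
    sd = if (length(values) > 1L) stats::sd(values) else 0)
}

#' Format a metrics table as percentages with one decimal place
#'
#' Renders a mean +/- SD metric table in the style used for reporting
#' cross-validation results (values in percent, one decimal).
#'
#' @param tab Data frame with columns \code{<metric>_mean} and
#'   \code{<metric>_sd} for the five metrics.
#' @return Character matrix of "xx.x +/- y.y" strings.
#' @export
format_percent_table <- function(tab) {
  out <- sapply(metric_names, function(mn) {
    sprintf("%.1f ± %.1f", 100 * tab[[paste0(mn, "_mean")]],
            100 * tab[[paste0(mn, "_sd")]])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, metric_names))
  out
}
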