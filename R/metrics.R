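#' Classification performance report
#'
#' Confusion counts and the five standard rates — accuracy, sensitivity
#' (malignant recall), specificity (benign recall), positive predictive
#' value, negative predictive value — as percentages, plus a trapezoidal
#' AUC over the ROC of the continuous score when one is supplied. Rates are
#' kept at full precision; rounding to 2 decimals happens only in the print
#' method / [format_eval_report()]. A rate whose denominator is zero (e.g.
#' sensitivity with no malignant cases) is `NA`, not 0.
#'
#' @param predicted 0/1 (or `"benign"`/`"malignant"`) predicted classes.
#' @param labels true classes, same coding.
#' @param scores optional continuous malignancy scores for the ROC/AUC.
#' @return An `eval_report` list: `tp, fn, fp, tn`, `accuracy, sensitivity,
#'   specificity, ppv, npv` (percent), and `auc`/`roc` when scores are given.
#' @export
eval_metrics <- function(predicted, labels, scores = NULL) {
  to01 <- function(v) if (is.numeric(v)) as.integer(v) else
    as.integer(factor(v, levels = c("benign", "malignant"))) - 1L
  pr <- to01(predicted); y <- to01(labels)
  if (length(pr) != length(y)) stop("prediction and label lengths differ")
  tp <- sum(pr == 1L & y == 1L); fn <- sum(pr == 0L & y == 1L)
  fp <- sum(pr == 1L & y == 0L); tn <- sum(pr == 0L & y == 0L)
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- list(tp = tp, fn = fn, fp = fp, tn = tn,
              accuracy = rate(tp + tn, tp + fn + fp + tn),
              sensitivity = rate(tp, tp + fn),
              specificity = rate(tn, tn + fp),
              ppv = rate(tp, tp + fp),
              npv = rate(tn, tn + fn))
  if (!is.null(scores)) {
    r <- roc_points(scores, y)
    out$roc <- r
    out$auc <- auc_trapezoid(r)
  }
  structure(out, class = "eval_report")
}

#' ROC curve of a continuous score
#'
#' One operating point per distinct threshold (all finite score values plus
#' the extremes), each classifying `score > threshold` as malignant.
#'
#' @param scores continuous malignancy scores.
#' @param labels 0/1 true classes.
#' @return data.frame `fpr, tpr, threshold`, ordered by ascending FPR.
#' @export
roc_points <- function(scores, labels) {
  y <- if (is.numeric(labels)) as.integer(labels) else
    as.integer(factor(labels, levels = c("benign", "malignant"))) - 1L
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  np <- sum(y == 1L); nn <- sum(y == 0L)
  tpr <- vapply(th, function(t) if (np == 0) NA_real_ else sum(scores > t & y == 1L) / np,
                numeric(1))
  fpr <- vapply(th, function(t) if (nn == 0) NA_real_ else sum(scores > t & y == 0L) / nn,
                numeric(1))
  data.frame(fpr = fpr, tpr = tpr, threshold = th)[order(fpr, tpr), ]
}

#' Trapezoidal area under an ROC curve
#'
#' @param roc data.frame from [roc_points()].
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(roc) {
  f <- roc$fpr; t <- roc$tpr
  sum(diff(f) * (head(t, -1) + tail(t, -1)) / 2)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(format_eval_report(x), sep = "\n")
  invisible(x)
}

#' Render an evaluation report as a table (2-decimal rates)
#'
#' @param x an `eval_report`.
#' @return Character vector of formatted lines.
#' @export
format_eval_report <- function(x) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)
  c(sprintf("Confusion: TP=%d FN=%d FP=%d TN=%d", x$tp, x$fn, x$fp, x$tn),
    sprintf("Acc (%%)  %s", fmt(x$accuracy)),
    sprintf("Sen (%%)  %s", fmt(x$sensitivity)),
    sprintf("Spec (%%) %s", fmt(x$specificity)),
    sprintf("PPV (%%)  %s", fmt(x$ppv)),
    sprintf("NPV (%%)  %s", fmt(x$npv)),
    if (!is.null(x$auc)) sprintf("AUC      %.4f", x$auc))
}
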