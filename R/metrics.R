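#' Confusion counts from binary predictions
#'
#' @param pred logical/0-1 predictions.
#' @param truth logical/0-1 ground truth.
#' @return named integer vector `c(TP =, FP =, FN =, TN =)`.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  stopifnot(length(pred) == length(truth))
  c(TP = sum(pred & truth), FP = sum(pred & !truth),
    FN = sum(!pred & truth), TN = sum(!pred & !truth))
}

#' Performance metrics from confusion counts
#'
#' Computes the reported metric set: F1-score, sensitivity (recall), PPV
#' (precision), FOR (false omission rate, `FN/(FN+TN)`, equal to 1 - NPV)
#' and FPR (`FP/(FP+TN)`, equal to 1 - specificity). A metric whose
#' denominator is zero is returned as `NA` and listed in the `undefined`
#' attribute rather than raising an error.
#'
#' @param counts named vector with `TP`, `FP`, `FN`, `TN` (see
#'   [confusion_counts()]).
#' @return named list with `f1`, `sensitivity`, `ppv`, `for_`, `fpr`,
#'   `npv`, `specificity`, `counts`, `undefined` (character vector).
#' @export
compute_metrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  fn <- counts[["FN"]]; tn <- counts[["TN"]]
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  ppv <- ratio(tp, tp + fp)
  f1 <- if ((2 * tp + fp + fn) > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  out <- list(
    f1 = f1,
    sensitivity = sens,
    ppv = ppv,
    for_ = ratio(fn, fn + tn),
    fpr = ratio(fp, fp + tn),
    npv = ratio(tn, fn + tn),
    specificity = ratio(tn, fp + tn),
    counts = counts
  )
  out$undefined <- names(out)[vapply(out[1:7], function(v) is.na(v),
                                     logical(1))]
  out
}

# metric of a confusion-count vector by name; vectorised versions used by
# the resampling machinery operate on TP/FP/FN/TN vectors directly
metric_from_counts <- function(tp, fp, fn, tn, metric) {
  switch(metric,
    f1 = ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), NA_real_),
    sensitivity = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_),
    ppv = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    for_ = ifelse(fn + tn > 0, fn / (fn + tn), NA_real_),
    fpr = ifelse(fp + tn > 0, fp / (fp + tn), NA_real_),
    stop(sprintf("unknown metric '%s'", metric))
  )
}

#' Evaluate binary predictions with one call
#'
#' @param pred,truth logical vectors.
#' @param metric metric name: one of `"f1"`, `"sensitivity"`, `"ppv"`,
#'   `"for_"`, `"fpr"`.
#' @return numeric scalar.
#' @export
binary_metric <- function(pred, truth, metric = "f1") {
  cc <- confusion_counts(pred, truth)
  metric_from_counts(cc[["TP"]], cc[["FP"]], cc[["FN"]], cc[["TN"]], metric)
}

#' ROC and precision-recall curves
#'
#' Computes curve points at every distinct score threshold (decision:
#' `score >= t`), plus the trivial all-negative endpoint. The ROC curve is
#' a step function from (0,0) to (1,1); the precision-recall curve uses the
#' convention that PPV at full recall (threshold at the minimum score)
#' equals the class prevalence when every call is predicted positive.
#'
#' @param scores numeric scores.
#' @param labels logical/0-1 ground truth; both classes must be present.
#' @return data.frame with columns `threshold`, `tp`, `fp`, `sensitivity`
#'   (= recall = TPR), `fpr`, `ppv`, ordered by descending threshold.
#' @export
roc_pr_points <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("curves require both classes in `labels`")
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cum_tp <- cumsum(y); cum_fp <- cumsum(!y)
  last <- c(diff(s) != 0, TRUE)  # last index within each tied block
  tp <- c(0, cum_tp[last]); fp <- c(0, cum_fp[last])
  thr <- c(Inf, s[last])
  data.frame(
    threshold = thr,
    tp = tp, fp = fp,
    sensitivity = tp / n_pos,
    fpr = fp / n_neg,
    ppv = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  )
}

#' Area under the ROC curve (trapezoidal)
#'
#' @inheritParams roc_pr_points
#' @return numeric scalar in \[0,1\].
#' @export
auroc <- function(scores, labels) {
  pts <- roc_pr_points(scores, labels)
  sum(diff(pts$fpr) * (head(pts$sensitivity, -1) +
                         pts$sensitivity[-1]) / 2)
}
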