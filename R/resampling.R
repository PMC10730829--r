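new_permutation_result <- function(observed, p_value, n_perm, test_type,
                                   alternative, metric, n_skipped = 0L) {
  structure(list(observed_stat = observed, p_value = p_value,
                 n_permutations = n_perm, test_type = test_type,
                 alternative = alternative, metric = metric,
                 n_skipped = n_skipped),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("%s one-sided permutation test (%s, %s): stat = %.4g, p = %.4g (%d permutations)\n",
              x$test_type, x$metric, x$alternative, x$observed_stat,
              x$p_value, x$n_permutations))
  invisible(x)
}

as_run_matrix <- function(pred, n) {
  if (is.null(dim(pred))) pred <- matrix(as.numeric(pred), ncol = 1)
  else pred <- matrix(as.numeric(pred), nrow = nrow(pred))
  stopifnot(nrow(pred) == n)
  pred
}

#' One-sided paired approximate permutation test
#'
#' Compares two prediction systems evaluated on the *same* calls. The
#' statistic is the (run-averaged) metric of A minus that of B. The null
#' distribution is approximated by randomly swapping each call's (A, B)
#' prediction pair with probability 1/2; when either side has several
#' training runs, the same swap mask is applied to every run and the
#' statistic is averaged over runs. A single-run system (e.g. the
#' call-taker) is broadcast across the other side's runs. The p-value uses
#' add-one smoothing: `p = (1 + #\{null >= observed\}) / (1 + n_perm)` for
#' `alternative = "greater"`.
#'
#' @param pred_a,pred_b logical/0-1 vectors, or matrices with one column
#'   per training run.
#' @param labels ground-truth labels for the shared calls.
#' @param metric metric name (see [binary_metric()]).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param alternative `"greater"` tests whether A beats B; `"less"` the
#'   reverse. The direction must be chosen a priori by the caller.
#' @return a `permutation_result`.
#' @export
paired_permutation_test <- function(pred_a, pred_b, labels, metric = "f1",
                                    n_perm = 10000L, seed = 1L,
                                    alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  y <- as.numeric(as.logical(labels))
  n <- length(y)
  A <- as_run_matrix(pred_a, n)
  B <- as_run_matrix(pred_b, n)
  if (ncol(A) != ncol(B)) {
    if (ncol(A) == 1L) A <- A[, rep(1L, ncol(B)), drop = FALSE]
    else if (ncol(B) == 1L) B <- B[, rep(1L, ncol(A)), drop = FALSE]
    else stop("run counts of pred_a and pred_b must match (or be 1)")
  }
  R <- ncol(A)
  run_stat <- function(M) {
    tp <- colSums(M * y); fp <- colSums(M * (1 - y))
    fn <- colSums((1 - M) * y); tn <- colSums((1 - M) * (1 - y))
    metric_from_counts(tp, fp, fn, tn, metric)
  }
  observed <- mean(run_stat(A)) - mean(run_stat(B))

  yA <- A * y; nA <- A * (1 - y)
  yB <- B * y; nB <- B * (1 - y)
  base <- c(colSums(yA), colSums(nA), colSums(yB), colSums(nB))
  n_pos <- sum(y); n_neg <- n - n_pos

  null_stats <- numeric(0)
  with_seed(seed, {
    remaining <- n_perm
    chunk <- min(2000L, n_perm)
    while (remaining > 0) {
      P <- min(chunk, remaining)
      M <- matrix(runif(n * P) < 0.5, n, P)  # TRUE = swap this call
      storage.mode(M) <- "double"
      ## crossprod once against all four term sets, per run
      swap_yA <- crossprod(M, yA); swap_nA <- crossprod(M, nA)
      swap_yB <- crossprod(M, yB); swap_nB <- crossprod(M, nB)
      tpA <- sweep(-swap_yA + swap_yB, 2, colSums(yA), `+`)
      fpA <- sweep(-swap_nA + swap_nB, 2, colSums(nA), `+`)
      tpB <- sweep(-swap_yB + swap_yA, 2, colSums(yB), `+`)
      fpB <- sweep(-swap_nB + swap_nA, 2, colSums(nB), `+`)
      statA <- metric_from_counts(tpA, fpA, n_pos - tpA, n_neg - fpA, metric)
      statB <- metric_from_counts(tpB, fpB, n_pos - tpB, n_neg - fpB, metric)
      null_stats <- c(null_stats,
                      rowMeans(matrix(statA, P, R)) -
                        rowMeans(matrix(statB, P, R)))
      remaining <- remaining - P
    }
  })
  skipped <- sum(is.na(null_stats))
  ns <- null_stats[!is.na(null_stats)]
  hits <- if (alternative == "greater") sum(ns >= observed)
          else sum(ns <= observed)
  p <- (1 + hits) / (1 + length(ns))
  new_permutation_result(observed, p, n_perm, "paired", alternative, metric,
                         skipped)
}

#' One-sided independent approximate permutation test
#'
#' Compares predictions on two *disjoint* call subsets (e.g. male vs
#' female, or the primary test set vs the no-category side set). The
#' statistic is the (run-averaged) metric on X minus that on Y; the null
#' reassigns calls to the two groups uniformly at random preserving group
#' sizes, using the same reassignment for every run. Null replicates where
#' the metric is undefined in either group are skipped and counted.
#'
#' @param pred_x,pred_y predictions on the two groups (vectors or
#'   run-matrices with matching run counts, broadcast as in the paired
#'   test).
#' @param labels_x,labels_y ground truth per group.
#' @inheritParams paired_permutation_test
#' @return a `permutation_result`.
#' @export
independent_permutation_test <- function(pred_x, labels_x, pred_y, labels_y,
                                         metric = "f1", n_perm = 10000L,
                                         seed = 1L,
                                         alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(labels_y) == 0 || length(labels_x) == 0) {
    stop("both groups must be non-empty")
  }
  yx <- as.numeric(as.logical(labels_x))
  yy <- as.numeric(as.logical(labels_y))
  X <- as_run_matrix(pred_x, length(yx))
  Y <- as_run_matrix(pred_y, length(yy))
  if (ncol(X) != ncol(Y)) {
    if (ncol(X) == 1L) X <- X[, rep(1L, ncol(Y)), drop = FALSE]
    else if (ncol(Y) == 1L) Y <- Y[, rep(1L, ncol(X)), drop = FALSE]
    else stop("run counts of pred_x and pred_y must match (or be 1)")
  }
  R <- ncol(X)
  nx <- length(yx); ny <- length(yy); n <- nx + ny
  pred <- rbind(X, Y)
  y <- c(yx, yy)
  run_stat <- function(M, yv) {
    tp <- colSums(M * yv); fp <- colSums(M * (1 - yv))
    fn <- colSums((1 - M) * yv); tn <- colSums((1 - M) * (1 - yv))
    metric_from_counts(tp, fp, fn, tn, metric)
  }
  observed <- mean(run_stat(X, yx)) - mean(run_stat(Y, yy))

  yp <- pred * y          # n x R
  np <- pred * (1 - y)
  tot_yp <- colSums(yp); tot_np <- colSums(np)
  tot_pos <- sum(y)

  null_stats <- numeric(0)
  with_seed(seed, {
    remaining <- n_perm
    chunk <- max(1L, min(1000L, n_perm))
    while (remaining > 0) {
      P <- min(chunk, remaining)
      G <- matrix(0, n, P)
      for (p in seq_len(P)) G[sample.int(n, nx), p] <- 1
      tp_x <- crossprod(G, yp); fp_x <- crossprod(G, np)  # P x R
      pos_x <- drop(crossprod(G, y))                      # positives in X
      fn_x <- pos_x - tp_x
      tn_x <- (nx - pos_x) - fp_x
      tp_y <- sweep(-tp_x, 2, tot_yp, `+`)
      fp_y <- sweep(-fp_x, 2, tot_np, `+`)
      fn_y <- (tot_pos - pos_x) - tp_y
      tn_y <- (ny - (tot_pos - pos_x)) - fp_y
      sx <- metric_from_counts(tp_x, fp_x, fn_x, tn_x, metric)
      sy <- metric_from_counts(tp_y, fp_y, fn_y, tn_y, metric)
      null_stats <- c(null_stats,
                      rowMeans(matrix(sx, P, R)) - rowMeans(matrix(sy, P, R)))
      remaining <- remaining - P
    }
  })
  skipped <- sum(is.na(null_stats))
  ns <- null_stats[!is.na(null_stats)]
  hits <- if (alternative == "greater") sum(ns >= observed)
          else sum(ns <= observed)
  p <- (1 + hits) / (1 + length(ns))
  new_permutation_result(observed, p, n_perm, "independent", alternative,
                         metric, skipped)
}

#' Bootstrap confidence interval for a metric
#'
#' Percentile bootstrap over calls: each replicate resamples calls with
#' replacement (shared across training runs), computes the metric per run
#' on the resampled calls, and averages over runs. Replicates where the
#' metric is undefined for any run are skipped and counted.
#'
#' @param preds predictions: logical/0-1 vector or matrix with one column
#'   per training run.
#' @param labels ground-truth labels.
#' @param metric metric name (see [binary_metric()]).
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return list with `ci_low`, `ci_high`, `mean` (run-averaged point
#'   estimate), `replicates` (the replicate statistics), `n_skipped`.
#' @export
bootstrap_ci <- function(preds, labels, metric = "f1", n_boot = 1000L,
                         seed = 1L, conf = 0.95) {
  y <- as.numeric(as.logical(labels))
  n <- length(y)
  A <- as_run_matrix(preds, n)
  R <- ncol(A)
  yA <- A * y; nA <- A * (1 - y)
  point <- mean(metric_from_counts(colSums(yA), colSums(nA),
                                   sum(y) - colSums(yA),
                                   (n - sum(y)) - colSums(nA), metric))
  reps <- numeric(0)
  with_seed(seed, {
    remaining <- n_boot
    chunk <- max(1L, min(250L, ceiling(2e7 / n)))
    while (remaining > 0) {
      P <- min(chunk, remaining)
      W <- rmultinom(P, n, rep(1 / n, n))  # n x P resampling weights
      storage.mode(W) <- "double"
      tp <- crossprod(W, yA); fp <- crossprod(W, nA)   # P x R
      pos <- drop(crossprod(W, y))
      fn <- pos - tp
      tn <- (n - pos) - fp
      s <- metric_from_counts(tp, fp, fn, tn, metric)  # P x R values
      reps <- c(reps, rowMeans(matrix(s, P, R)))
      remaining <- remaining - P
    }
  })
  skipped <- sum(is.na(reps))
  reps_ok <- reps[!is.na(reps)]
  qs <- quantile(reps_ok, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                 names = FALSE, type = 7)
  list(ci_low = qs[1], ci_high = qs[2], mean = point,
       replicates = reps_ok, n_skipped = skipped)
}

#' Aggregate metrics over training runs
#'
#' Computes each run's metric set from its predictions, then reports the
#' per-metric mean over runs together with the rounded mean confusion
#' counts (the form the confusion matrices are reported in).
#'
#' @param preds matrix of predictions, one column per run (or a vector for
#'   a single run).
#' @param labels ground-truth labels.
#' @return list with `mean` (named numeric of mean metrics), `per_run`
#'   (data.frame, one row per run), `counts` (rounded mean confusion
#'   counts), `n_runs`.
#' @export
aggregate_runs <- function(preds, labels) {
  y <- as.logical(labels)
  A <- as_run_matrix(preds, length(y))
  per_run <- do.call(rbind, lapply(seq_len(ncol(A)), function(r) {
    m <- compute_metrics(confusion_counts(A[, r] == 1, y))
    data.frame(run = r, f1 = m$f1, sensitivity = m$sensitivity,
               ppv = m$ppv, for_ = m$for_, fpr = m$fpr,
               TP = m$counts[["TP"]], FP = m$counts[["FP"]],
               FN = m$counts[["FN"]], TN = m$counts[["TN"]])
  }))
  metric_cols <- c("f1", "sensitivity", "ppv", "for_", "fpr")
  list(
    mean = colMeans(per_run[metric_cols]),
    per_run = per_run,
    counts = round(colMeans(per_run[c("TP", "FP", "FN", "TN")])),
    n_runs = ncol(A)
  )
}
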