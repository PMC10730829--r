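#' Thresholds matching a reference sensitivity and PPV
#'
#' Scans the finite set of candidate thresholds (the observed scores plus 0
#' and 1; decisions are `score >= t`) and returns `t_sens`, the largest
#' threshold whose sensitivity is still at least `ref_sens`, and `t_ppv`,
#' the smallest threshold whose PPV reaches `ref_ppv`. Exact equality is
#' generally unattainable on a finite sample, so the ">= with extremal
#' selection" convention defines "matching".
#'
#' @param scores numeric scores in \[0,1\].
#' @param labels logical/0-1 ground truth (needs both classes).
#' @param ref_sens,ref_ppv reference operating point.
#' @return named numeric `c(t_sens =, t_ppv =)`.
#' @export
find_matching_thresholds <- function(scores, labels, ref_sens, ref_ppv) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("calibration needs at least one positive and one negative label")
  }
  stopifnot_fraction(ref_sens, "ref_sens")
  stopifnot_fraction(ref_ppv, "ref_ppv")
  ## candidates: the observed scores plus 1. A zero candidate would be
  ## redundant: decisions are `score >= t`, so thresholding at the minimum
  ## observed score already predicts everything positive, and keeping
  ## candidates strictly positive keeps the harmonic mean well defined.
  cand <- sort(unique(c(scores, 1)))
  n_pos <- sum(labels)
  ## decisions: positive iff score >= t
  ord <- order(scores)
  s_sorted <- scores[ord]
  cum_pos <- cumsum(as.numeric(labels[ord]))
  k_lt <- findInterval(cand, s_sorted, left.open = TRUE)  # #{score < t}
  pos_lt <- ifelse(k_lt == 0, 0, cum_pos[pmax(k_lt, 1)])
  pos_ge <- n_pos - pos_lt
  all_ge <- length(scores) - k_lt
  sens <- pos_ge / n_pos
  ppv <- ifelse(all_ge > 0, pos_ge / all_ge, NA_real_)
  ok_sens <- which(sens >= ref_sens)
  t_sens <- cand[max(ok_sens)]
  ok_ppv <- which(!is.na(ppv) & ppv >= ref_ppv)
  if (length(ok_ppv) == 0) {
    stop(sprintf(
      "reference PPV %.4g unattainable: maximum attainable PPV is %.4g",
      ref_ppv, max(ppv, na.rm = TRUE)), call. = FALSE)
  }
  t_ppv <- cand[min(ok_ppv)]
  c(t_sens = t_sens, t_ppv = t_ppv)
}

#' Harmonic mean of two calibration thresholds
#'
#' The per-member decision threshold is the harmonic mean of the threshold
#' matching call-taker sensitivity and the threshold matching call-taker
#' PPV: `2 * t_sens * t_ppv / (t_sens + t_ppv)`.
#'
#' @param t_sens,t_ppv thresholds in (0,1\].
#' @return numeric scalar.
#' @export
harmonic_threshold <- function(t_sens, t_ppv) {
  if (any(c(t_sens, t_ppv) <= 0)) {
    stop("harmonic_threshold() requires strictly positive thresholds")
  }
  2 * t_sens * t_ppv / (t_sens + t_ppv)
}

#' Calibrate ensemble member thresholds against the call-taker
#'
#' For each ensemble member, finds the thresholds matching the call-taker's
#' sensitivity and PPV on a calibration set (the validation split in the
#' full pipeline) and sets the member threshold tau_n to their harmonic
#' mean.
#'
#' @param ensemble a `strokecall_ensemble`.
#' @param X,labels calibration features and ground-truth labels.
#' @param ref_sens,ref_ppv call-taker operating point (defaults 0.527 /
#'   0.171).
#' @return object of class `threshold_set`: `tau`, `t_sens`, `t_ppv`
#'   (per-member vectors) and the reference values.
#' @export
calibrate_ensemble <- function(ensemble, X, labels,
                               ref_sens = 0.527, ref_ppv = 0.171) {
  logits <- ensemble_member_logits(ensemble, X)
  t_sens <- numeric(ncol(logits)); t_ppv <- numeric(ncol(logits))
  for (k in seq_len(ncol(logits))) {
    tt <- find_matching_thresholds(sigmoid(logits[, k]), labels,
                                   ref_sens, ref_ppv)
    t_sens[k] <- tt["t_sens"]; t_ppv[k] <- tt["t_ppv"]
  }
  threshold_set(mapply(harmonic_threshold, t_sens, t_ppv),
                t_sens, t_ppv, ref_sens, ref_ppv)
}

#' Construct a threshold set
#'
#' @param tau per-member decision thresholds in (0,1).
#' @param t_sens,t_ppv the matched thresholds tau is the harmonic mean of.
#' @param ref_sens,ref_ppv reference operating point used.
#' @return object of class `threshold_set`.
#' @export
threshold_set <- function(tau, t_sens = NULL, t_ppv = NULL,
                          ref_sens = NA_real_, ref_ppv = NA_real_) {
  if (any(tau <= 0 | tau >= 1)) {
    stop("member thresholds tau must lie strictly inside (0,1)")
  }
  structure(list(tau = as.numeric(tau), t_sens = t_sens, t_ppv = t_ppv,
                 ref_sens = ref_sens, ref_ppv = ref_ppv),
            class = "threshold_set")
}

#' Centred ensemble score
#'
#' Each member's logit is centred by subtracting the logit of its
#' calibrated threshold, so that every member shares the decision threshold
#' 0.5; the ensemble score is the sigmoid of the mean centred logit:
#' `sigmoid(mean_n(z_n - logit(tau_n)))`. A call is predicted stroke
#' positive when the score is at least 0.5.
#'
#' @param member_logits numeric matrix (calls x members) or vector (one
#'   call).
#' @param thresholds a [threshold_set()] (or numeric vector of tau values).
#' @return numeric vector of ensemble scores in (0,1).
#' @export
ensemble_score <- function(member_logits, thresholds) {
  tau <- if (inherits(thresholds, "threshold_set")) thresholds$tau
         else as.numeric(thresholds)
  if (any(tau <= 0 | tau >= 1)) {
    stop("member thresholds tau must lie strictly inside (0,1)")
  }
  if (is.null(dim(member_logits))) {
    member_logits <- matrix(member_logits, nrow = 1)
  }
  stopifnot(ncol(member_logits) == length(tau))
  centred <- sweep(member_logits, 2, logit(tau))
  sigmoid(rowMeans(centred))
}

#' Serialize / load a threshold set as JSON
#'
#' @param thresholds a `threshold_set`.
#' @param path file path.
#' @export
write_threshold_set <- function(thresholds, path) {
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_threshold_set
#' @export
read_threshold_set <- function(path) {
  obj <- jsonlite::fromJSON(path)
  threshold_set(obj$tau, obj$t_sens, obj$t_ppv, obj$ref_sens, obj$ref_ppv)
}
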