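#' Ground-truth stroke label for a single call
#'
#' A call is ground-truth stroke positive when some registry entry shares its
#' patient id, is not a subarachnoid haemorrhage (SAH), and has an onset time
#' within a window around the call start (default 72 hours before to 24
#' hours after, both endpoints included). Calls whose only qualifying
#' matches are SAH entries are negative; a call with both SAH and non-SAH
#' qualifying entries is positive. When several entries qualify, the one
#' with onset nearest the call start is returned.
#'
#' @param call a single-row data.frame (or list) with `patient_id` and
#'   `call_start`.
#' @param registry data.frame with `patient_id`, `onset_time`, `stroke_type`.
#' @param window_before_h,window_after_h window half-widths in hours.
#' @return list with `positive` (logical) and `entry` (one-row data.frame or
#'   `NULL`).
#' @export
ground_truth_label <- function(call, registry,
                               window_before_h = 72, window_after_h = 24) {
  pid <- call$patient_id
  if (is.null(pid) || length(pid) != 1 || is.na(pid)) {
    warning("call has no patient_id; labelling as non-stroke")
    return(list(positive = FALSE, entry = NULL))
  }
  cand <- registry[registry$patient_id == pid &
                     registry$stroke_type != "SAH", , drop = FALSE]
  if (nrow(cand) == 0) return(list(positive = FALSE, entry = NULL))
  off_h <- as.numeric(difftime(cand$onset_time, call$call_start,
                               units = "hours"))
  keep <- off_h >= -window_before_h & off_h <= window_after_h
  if (!any(keep)) return(list(positive = FALSE, entry = NULL))
  cand <- cand[keep, , drop = FALSE]
  off_h <- off_h[keep]
  list(positive = TRUE, entry = cand[which.min(abs(off_h)), , drop = FALSE])
}

#' Call-taker stroke label
#'
#' A call counts as call-taker stroke positive only when the stroke
#' diagnostic category was selected during the call *and* an ambulance with
#' an appropriate level of response was dispatched.
#'
#' @param stroke_category_selected logical (vectorised).
#' @param ambulance_dispatched_appropriate logical (vectorised).
#' @return logical vector.
#' @export
calltaker_label <- function(stroke_category_selected,
                            ambulance_dispatched_appropriate) {
  as.logical(stroke_category_selected) &
    as.logical(ambulance_dispatched_appropriate)
}

#' Cross-reference calls with the stroke registry
#'
#' Vectorised linkage of a call table against a registry table: adds
#' `ground_truth` (non-SAH entry within the onset window), the matched
#' entry's onset offset and stroke type, and the call-taker label.
#'
#' @param calls data.frame of call records.
#' @param registry data.frame of registry entries.
#' @inheritParams ground_truth_label
#' @return `calls` with columns `ground_truth`, `matched_onset_offset_h`,
#'   `matched_stroke_type`, `calltaker_positive` appended.
#' @export
link_cohort <- function(calls, registry,
                        window_before_h = 72, window_after_h = 24) {
  non_sah <- registry[registry$stroke_type != "SAH", , drop = FALSE]
  m <- match(calls$patient_id, non_sah$patient_id)
  # match() takes the first entry per patient; for the synthetic cohorts one
  # entry per patient is the rule, but resolve duplicates nearest-first to
  # honour the documented tie rule.
  dup_pids <- unique(non_sah$patient_id[duplicated(non_sah$patient_id)])
  off_h <- rep(NA_real_, nrow(calls))
  type <- rep(NA_character_, nrow(calls))
  hit <- !is.na(m)
  off_h[hit] <- as.numeric(difftime(non_sah$onset_time[m[hit]],
                                    calls$call_start[hit], units = "hours"))
  type[hit] <- non_sah$stroke_type[m[hit]]
  if (length(dup_pids)) {
    for (i in which(calls$patient_id %in% dup_pids)) {
      res <- ground_truth_label(calls[i, ], registry,
                                window_before_h, window_after_h)
      if (res$positive) {
        off_h[i] <- as.numeric(difftime(res$entry$onset_time,
                                        calls$call_start[i], units = "hours"))
        type[i] <- res$entry$stroke_type
      } else {
        off_h[i] <- NA_real_
        type[i] <- NA_character_
      }
    }
  }
  in_window <- !is.na(off_h) & off_h >= -window_before_h &
    off_h <= window_after_h
  calls$ground_truth <- in_window
  calls$matched_onset_offset_h <- ifelse(in_window, off_h, NA_real_)
  calls$matched_stroke_type <- ifelse(in_window, type, NA_character_)
  calls$calltaker_positive <- calltaker_label(
    calls$stroke_category_selected, calls$ambulance_dispatched_appropriate)
  calls
}

#' Assign calls to train folds, validation, and test subsets
#'
#' Reproduces the study's splitting scheme: helpline calls from the test
#' year form the test set if they carry a diagnostic category, otherwise the
#' `test_no_category` side set; earlier helpline calls are divided into a
#' validation subset and `n_folds` training folds by stratified sampling on
#' the pair (ground-truth label, category present). Calls without a
#' diagnostic category never enter validation or test. Emergency-line calls
#' are training-only (`train_emergency`), and emergency-line calls from the
#' test year are discarded entirely (`excluded`) to avoid temporal overlap.
#'
#' @param calls linked call table (see [link_cohort()]); must have
#'   `ground_truth`, `line`, `call_start`, `diagnostic_category`.
#' @param test_year calendar year reserved for testing.
#' @param n_folds number of training folds (default 5).
#' @param validation_fraction fraction of eligible pre-test-year helpline
#'   calls held out for validation (default 0.1).
#' @param seed integer seed for the stratified shuffle.
#' @return character vector of subset labels, one per call, from
#'   `train_fold_1..n_folds`, `validation`, `test`, `test_no_category`,
#'   `train_emergency`, `excluded`.
#' @export
split_dataset <- function(calls, test_year, n_folds = 5,
                          validation_fraction = 0.1, seed = 1L) {
  year <- as.integer(format(calls$call_start, "%Y", tz = "UTC"))
  has_cat <- !is.na(calls$diagnostic_category)
  helpline <- calls$line == "helpline"
  subset <- rep(NA_character_, nrow(calls))

  subset[!helpline & year == test_year] <- "excluded"
  subset[!helpline & year != test_year] <- "train_emergency"
  subset[helpline & year == test_year & has_cat] <- "test"
  subset[helpline & year == test_year & !has_cat] <- "test_no_category"

  pool <- which(helpline & year < test_year)
  strata <- interaction(calls$ground_truth[pool], has_cat[pool], drop = TRUE)
  ## ground-truth-positive strata are processed first and the round-robin
  ## counter persists across strata, so the per-fold positive counts stay
  ## within one call of equal even though positives span several strata
  lvls <- levels(strata)
  lvls <- c(lvls[startsWith(lvls, "TRUE")], lvls[startsWith(lvls, "FALSE")])
  with_seed(seed, {
    counter <- 0L
    for (s in lvls) {
      idx <- pool[strata == s]
      if (length(idx) < n_folds) {
        stop(sprintf(
          "stratum '%s' has %d calls, fewer than n_folds = %d",
          s, length(idx), n_folds), call. = FALSE)
      }
      idx <- sample(idx)
      stratum_has_cat <- has_cat[idx[1]]
      n_val <- if (stratum_has_cat) round(validation_fraction * length(idx))
               else 0L
      if (n_val > 0) subset[idx[seq_len(n_val)]] <- "validation"
      rest <- idx[setdiff(seq_along(idx), seq_len(n_val))]
      fold_id <- ((seq_along(rest) - 1L + counter) %% n_folds) + 1L
      subset[rest] <- sprintf("train_fold_%d", fold_id)
      counter <- (counter + length(rest)) %% n_folds
    }
  })
  subset
}
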