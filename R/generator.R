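#' Default planted marker word lists
#'
#' Ten stroke-indicator tokens and ten distractor tokens used by the
#' synthetic transcript generator. The lists are seeded from English
#' translations of words that rank highly for stroke and non-stroke
#' predictions in real helpline-call attribution tables, so that occlusion
#' output on synthetic cohorts reads naturally.
#'
#' @return character vector of tokens.
#' @export
default_indicator_words <- function() {
  c("ambulance", "blood_clot", "left", "right", "double_vision",
    "suddenly", "arm", "stroke", "numb", "slurred_speech")
}

#' @rdname default_indicator_words
#' @export
default_distractor_words <- function() {
  c("tetanus", "pregnant", "cut", "bandage", "fever",
    "swollen", "prescription", "pneumonia", "stool", "inflammation")
}

#' Implied call-taker false positive rate
#'
#' Call-taker triage is reported as a sensitivity/PPV pair; together with the
#' stroke prevalence these imply the false positive rate through
#' `FPR = prev * sens * (1 - ppv) / ((1 - prev) * ppv)`. The generator
#' simulates call-taker positives from sensitivity and this implied FPR
#' rather than taking an FPR directly, mirroring how triage performance is
#' reported.
#'
#' @param prevalence stroke prevalence in (0,1).
#' @param sensitivity call-taker sensitivity in \[0,1\].
#' @param ppv call-taker positive predictive value in (0,1\].
#' @return implied FPR (numeric scalar).
#' @export
implied_calltaker_fpr <- function(prevalence, sensitivity, ppv) {
  stopifnot_fraction(prevalence, "prevalence", open = TRUE)
  stopifnot_fraction(sensitivity, "sensitivity")
  if (ppv <= 0 || ppv > 1) stop("`ppv` must lie in (0,1]")
  prevalence * sensitivity * (1 - ppv) / ((1 - prevalence) * ppv)
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic medical-helpline cohort: cohort size,
#' line mix, stroke prevalence, demographic structure, call-taker operating
#' point, registry onset-offset noise, and the transcript language model
#' (Zipf background lexicon plus planted indicator/distractor words).
#' Defaults emulate the published cohort table and call-taker row that the
#' analysis is benchmarked against: helpline stroke prevalence 0.25%,
#' call-taker sensitivity 52.7% and PPV 17.1%, stroke ages ~N(71, 13.4),
#' non-stroke ~N(44, 20) truncated to 18--105 years, 40% of calls without a
#' registered diagnostic category, and 5% of stroke onsets reported outside
#' the -72h/+24h linkage window.
#'
#' @param n_calls number of calls to generate.
#' @param stroke_prevalence helpline stroke-event prevalence, default 0.0025.
#' @param emergency_line_fraction fraction of calls on the emergency line.
#' @param emergency_prevalence stroke-event prevalence on the emergency line.
#' @param years calendar years the calls span; the last is the test year.
#' @param age_mean,age_sd named numeric `c(stroke=, non_stroke=)` for the
#'   truncated-normal age model.
#' @param age_range truncation bounds in years.
#' @param female_fraction named numeric `c(stroke=, non_stroke=)`.
#' @param unknown_sex_fraction fraction of calls with unrecorded sex.
#' @param calltaker_sensitivity,calltaker_ppv simulated call-taker operating
#'   point (defaults 0.527 / 0.171).
#' @param onset_offset_range hours of (onset - call_start) for in-window
#'   stroke calls; drawn uniformly.
#' @param onset_outside_fraction fraction of stroke onsets drawn outside the
#'   -72h/+24h window (exercises window exclusion downstream).
#' @param sah_fraction fraction of registry entries typed subarachnoid
#'   haemorrhage (excluded from ground truth downstream).
#' @param missing_category_fraction fraction of calls with no diagnostic
#'   category registered.
#' @param vocab_size,zipf_exponent background lexicon size and Zipf exponent.
#' @param indicator_words,indicator_rate,indicator_leak_rate stroke marker
#'   tokens, their per-word injection probability in stroke-call transcripts,
#'   and the (small) leak probability into non-stroke transcripts.
#' @param distractor_words,distractor_rate,distractor_leak_rate non-stroke
#'   marker tokens and rates, mirrored.
#' @param doc_length_mean,doc_length_size negative-binomial transcript length
#'   model (tokens).
#' @param token_noise_rate probability that a token is replaced by a random
#'   background word (crude stand-in for transcription errors); default 0.
#' @param seed integer; fully determines the generated cohort.
#' @return an object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_calls,
                             stroke_prevalence = 0.0025,
                             emergency_line_fraction = 0.0659,
                             emergency_prevalence = 0.025,
                             years = 2019:2021,
                             age_mean = c(stroke = 71, non_stroke = 44),
                             age_sd = c(stroke = 13.4, non_stroke = 20),
                             age_range = c(18, 105),
                             female_fraction = c(stroke = 0.461,
                                                 non_stroke = 0.555),
                             unknown_sex_fraction = 0.004,
                             calltaker_sensitivity = 0.527,
                             calltaker_ppv = 0.171,
                             onset_offset_range = c(-48, 12),
                             onset_outside_fraction = 0.05,
                             sah_fraction = 0.05,
                             missing_category_fraction = 0.40,
                             vocab_size = 250,
                             zipf_exponent = 1.05,
                             indicator_words = default_indicator_words(),
                             indicator_rate = 0.4,
                             indicator_leak_rate = 0.002,
                             distractor_words = default_distractor_words(),
                             distractor_rate = 0.15,
                             distractor_leak_rate = 0.01,
                             doc_length_mean = 40,
                             doc_length_size = 5,
                             token_noise_rate = 0,
                             seed = 1L) {
  stopifnot(is.numeric(n_calls), n_calls >= 1)
  stopifnot_fraction(stroke_prevalence, "stroke_prevalence", open = TRUE)
  stopifnot_fraction(emergency_line_fraction, "emergency_line_fraction")
  stopifnot_fraction(calltaker_sensitivity, "calltaker_sensitivity")
  stopifnot_fraction(calltaker_ppv, "calltaker_ppv")
  for (nm in c("onset_outside_fraction", "sah_fraction",
               "missing_category_fraction", "indicator_rate",
               "indicator_leak_rate", "distractor_rate",
               "distractor_leak_rate", "token_noise_rate",
               "unknown_sex_fraction")) {
    stopifnot_fraction(get(nm), nm)
  }
  fpr <- implied_calltaker_fpr(stroke_prevalence, calltaker_sensitivity,
                               calltaker_ppv)
  if (fpr > 1) {
    stop(sprintf(paste0(
      "infeasible call-taker configuration: prevalence %.4g, sensitivity ",
      "%.4g and PPV %.4g imply a false positive rate of %.4g > 1"),
      stroke_prevalence, calltaker_sensitivity, calltaker_ppv, fpr),
      call. = FALSE)
  }
  cfg <- list(
    n_calls = as.integer(n_calls),
    stroke_prevalence = stroke_prevalence,
    emergency_line_fraction = emergency_line_fraction,
    emergency_prevalence = emergency_prevalence,
    years = as.integer(years),
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    female_fraction = female_fraction,
    unknown_sex_fraction = unknown_sex_fraction,
    calltaker_sensitivity = calltaker_sensitivity,
    calltaker_ppv = calltaker_ppv,
    calltaker_fpr = fpr,
    onset_offset_range = onset_offset_range,
    onset_outside_fraction = onset_outside_fraction,
    sah_fraction = sah_fraction,
    missing_category_fraction = missing_category_fraction,
    vocab_size = as.integer(vocab_size),
    zipf_exponent = zipf_exponent,
    indicator_words = indicator_words,
    indicator_rate = indicator_rate,
    indicator_leak_rate = indicator_leak_rate,
    distractor_words = distractor_words,
    distractor_rate = distractor_rate,
    distractor_leak_rate = distractor_leak_rate,
    doc_length_mean = doc_length_mean,
    doc_length_size = doc_length_size,
    token_noise_rate = token_noise_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  cfg
}

#' Simulate call-taker triage labels
#'
#' Draws one binary triage label per call, positive with probability `sens`
#' for stroke calls and `fpr` for non-stroke calls, independently across
#' calls.
#'
#' @param truth logical vector of planted stroke status.
#' @param sens,fpr call-taker sensitivity and false positive rate in \[0,1\].
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return logical vector of call-taker positives, same length as `truth`.
#' @export
simulate_calltaker <- function(truth, sens, fpr, seed = NULL) {
  stopifnot_fraction(sens, "sens")
  stopifnot_fraction(fpr, "fpr")
  with_seed(seed, {
    p <- ifelse(truth, sens, fpr)
    rbinom(length(truth), 1L, p) == 1L
  })
}

# truncated normal via inverse-cdf sampling
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic helpline/emergency call cohort
#'
#' Produces call records, stroke-registry entries and token transcripts with
#' the statistical structure the downstream analysis assumes: rare stroke
#' calls on the helpline line (richer on the emergency line), age and sex
#' distributions that differ by stroke status, call-taker triage labels
#' realised at the configured sensitivity and implied FPR, onset offsets
#' partly outside the linkage window, SAH registry entries, calls with
#' missing diagnostic category, and Zipf background text with planted
#' indicator/distractor words. The whole cohort is a deterministic function
#' of `config$seed`.
#'
#' @param config a [generator_config()].
#' @return An object of class `strokecall_cohort`: a list with elements
#'   `calls` (data.frame of call records), `registry` (data.frame of registry
#'   entries), `transcripts` (named list of token vectors, by call id),
#'   `truth` (named logical, planted ground-truth-consistent stroke status)
#'   and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_calls
  call_id <- sprintf("C%07d", seq_len(n))
  patient_id <- sprintf("P%07d", seq_len(n))
  line <- ifelse(runif(n) < cfg$emergency_line_fraction,
                 "emergency", "helpline")
  prev <- ifelse(line == "emergency", cfg$emergency_prevalence,
                 cfg$stroke_prevalence)
  stroke_event <- runif(n) < prev

  ## timestamps uniform over the configured years
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", min(cfg$years)), tz = "UTC")
  t1 <- as.POSIXct(sprintf("%d-01-01 00:00:00", max(cfg$years) + 1L),
                   tz = "UTC")
  call_start <- t0 + runif(n, 0, as.numeric(difftime(t1, t0, units = "secs")))

  ## demographics by stroke status
  grp <- ifelse(stroke_event, "stroke", "non_stroke")
  age <- rtruncnorm(n, cfg$age_mean[grp], cfg$age_sd[grp],
                    cfg$age_range[1], cfg$age_range[2])
  sex <- ifelse(runif(n) < cfg$female_fraction[grp], "female", "male")
  sex[runif(n) < cfg$unknown_sex_fraction] <- "unknown"

  ## registry entries for stroke-event calls
  idx_ev <- which(stroke_event)
  n_ev <- length(idx_ev)
  outside <- runif(n_ev) < cfg$onset_outside_fraction
  offset_h <- runif(n_ev, cfg$onset_offset_range[1], cfg$onset_offset_range[2])
  if (any(outside)) {
    side <- runif(sum(outside)) < 0.5
    off_out <- ifelse(side, runif(sum(outside), -120, -73),
                      runif(sum(outside), 25, 72))
    offset_h[outside] <- off_out
  }
  stroke_type <- ifelse(
    runif(n_ev) < cfg$sah_fraction, "SAH",
    sample(c("ischaemic", "TIA", "haemorrhagic"), n_ev, replace = TRUE,
           prob = c(0.65, 0.25, 0.10)))
  registry <- data.frame(
    patient_id = patient_id[idx_ev],
    onset_time = call_start[idx_ev] + offset_h * 3600,
    stroke_type = stroke_type,
    stringsAsFactors = FALSE
  )

  ## planted truth is consistent with registry membership, the -72h/+24h
  ## window and the SAH exclusion applied downstream
  truth <- rep(FALSE, n)
  truth[idx_ev] <- offset_h >= -72 & offset_h <= 24 & stroke_type != "SAH"

  ## diagnostic category bookkeeping and simulated triage
  missing_cat <- runif(n) < cfg$missing_category_fraction
  ct_pos <- rep(FALSE, n)
  eligible <- which(!missing_cat)
  ct_pos[eligible] <- simulate_calltaker(truth[eligible],
                                         cfg$calltaker_sensitivity,
                                         cfg$calltaker_fpr)
  stroke_cat <- ct_pos
  # a small share of calls get the stroke category without an appropriately
  # prioritised ambulance; they must not count as call-taker positive
  cat_no_amb <- !missing_cat & !ct_pos & runif(n) < 0.01
  stroke_cat[cat_no_amb] <- TRUE
  ambulance <- ct_pos | (!stroke_cat & runif(n) < 0.05)

  other_codes <- c("respiratory", "cardiac", "trauma", "abdominal",
                   "infection", "psychiatric", "other")
  diagnostic_category <- ifelse(
    missing_cat, NA_character_,
    ifelse(stroke_cat, "stroke",
           sample(other_codes, n, replace = TRUE)))

  calls <- data.frame(
    call_id = call_id,
    patient_id = patient_id,
    line = line,
    call_start = call_start,
    age = round(age, 1),
    sex = sex,
    diagnostic_category = diagnostic_category,
    stroke_category_selected = stroke_cat,
    ambulance_dispatched_appropriate = ambulance,
    stringsAsFactors = FALSE
  )

  transcripts <- generate_transcripts(cfg, truth, call_id)

  structure(
    list(calls = calls, registry = registry, transcripts = transcripts,
         truth = setNames(truth, call_id), config = cfg),
    class = "strokecall_cohort"
  )
}

# Zipf background text plus planted marker words; returns a named list of
# token vectors. Assumes the caller set the RNG state.
generate_transcripts <- function(cfg, truth, call_id) {
  n <- length(truth)
  lexicon <- sprintf("w%03d", seq_len(cfg$vocab_size))
  zipf_p <- seq_len(cfg$vocab_size)^(-cfg$zipf_exponent)
  zipf_p <- zipf_p / sum(zipf_p)

  len <- pmax(5L, stats::rnbinom(n, size = cfg$doc_length_size,
                                 mu = cfg$doc_length_mean))
  bg <- sample(lexicon, sum(len), replace = TRUE, prob = zipf_p)
  doc_of_bg <- rep.int(seq_len(n), len)

  inject <- function(words, p_pos, p_neg, pos) {
    # counts[i, w]: copies of word w in document i
    p <- ifelse(pos, p_pos, p_neg)
    out_i <- integer(0); out_w <- integer(0)
    for (w in seq_along(words)) {
      hit <- which(runif(n) < p)
      cnt <- 1L + rbinom(length(hit), 1L, 0.4)  # 1 or 2 copies
      out_i <- c(out_i, rep.int(hit, cnt))
      out_w <- c(out_w, rep.int(w, sum(cnt)))
    }
    list(doc = out_i, token = words[out_w])
  }
  ind <- inject(cfg$indicator_words, cfg$indicator_rate,
                cfg$indicator_leak_rate, truth)
  dis <- inject(cfg$distractor_words, cfg$distractor_leak_rate,
                cfg$distractor_rate, truth)

  doc_all <- c(doc_of_bg, ind$doc, dis$doc)
  tok_all <- c(bg, ind$token, dis$token)
  if (cfg$token_noise_rate > 0) {
    noisy <- runif(length(tok_all)) < cfg$token_noise_rate
    tok_all[noisy] <- sample(lexicon, sum(noisy), replace = TRUE,
                             prob = zipf_p)
  }
  ## shuffle within documents: order by (doc, random key)
  key <- runif(length(doc_all))
  o <- order(doc_all, key)
  transcripts <- split(tok_all[o], factor(doc_all[o], levels = seq_len(n)))
  names(transcripts) <- call_id
  transcripts
}

#' @export
print.strokecall_cohort <- function(x, ...) {
  cat(sprintf(
    "<strokecall_cohort> %d calls (%d emergency-line), %d registry entries, %d stroke-positive\n",
    nrow(x$calls), sum(x$calls$line == "emergency"), nrow(x$registry),
    sum(x$truth)))
  invisible(x)
}

#' Write / read a cohort as plain-text files
#'
#' Serialises a synthetic cohort to `calls.csv`, `registry.csv`,
#' `transcripts.jsonl` (one JSON object per call: `call_id`, `tokens`) and
#' `config.yaml` inside `dir`; `read_cohort()` reconstructs the cohort.
#' Planted truth is stored as a `planted_stroke` column of `calls.csv`.
#'
#' @param cohort a `strokecall_cohort`.
#' @param dir directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` the
#'   cohort.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  calls <- cohort$calls
  calls$call_start <- format(calls$call_start, "%Y-%m-%dT%H:%M:%OSZ",
                             tz = "UTC")
  calls$planted_stroke <- unname(cohort$truth[calls$call_id])
  write.csv(calls, file.path(dir, "calls.csv"), row.names = FALSE, na = "")
  reg <- cohort$registry
  reg$onset_time <- format(reg$onset_time, "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  write.csv(reg, file.path(dir, "registry.csv"), row.names = FALSE)
  con <- file(file.path(dir, "transcripts.jsonl"), "w")
  on.exit(close(con))
  for (id in names(cohort$transcripts)) {
    writeLines(jsonlite::toJSON(
      list(call_id = id, tokens = cohort$transcripts[[id]]),
      auto_unbox = TRUE), con)
  }
  cfg <- cohort$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  calls <- read.csv(file.path(dir, "calls.csv"), stringsAsFactors = FALSE,
                    na.strings = "")
  calls$call_start <- as.POSIXct(calls$call_start,
                                 format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  truth <- setNames(as.logical(calls$planted_stroke), calls$call_id)
  calls$planted_stroke <- NULL
  for (col in c("stroke_category_selected", "ambulance_dispatched_appropriate"))
    calls[[col]] <- as.logical(calls[[col]])
  registry <- read.csv(file.path(dir, "registry.csv"),
                       stringsAsFactors = FALSE)
  registry$onset_time <- as.POSIXct(registry$onset_time,
                                    format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  lines <- readLines(file.path(dir, "transcripts.jsonl"))
  parsed <- lapply(lines, jsonlite::fromJSON)
  transcripts <- setNames(
    lapply(parsed, function(p) as.character(p$tokens)),
    vapply(parsed, function(p) p$call_id, character(1)))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  class(cfg) <- "generator_config"
  structure(list(calls = calls, registry = registry,
                 transcripts = transcripts, truth = truth, config = cfg),
            class = "strokecall_cohort")
}
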