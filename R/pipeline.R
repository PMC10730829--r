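#' Full pipeline configuration
#'
#' Bundles every stage's settings: generator, featurization, classifier,
#' calibration references and evaluation. Every stochastic stage derives
#' its own seed deterministically from the global `seed` plus the stage
#' name, so one integer reproduces the whole study.
#'
#' @param n_calls cohort size (default 50000, the package's standard
#'   synthetic study size).
#' @param n_runs number of randomly initialised training runs aggregated in
#'   evaluation (default 11; must be odd for the occlusion run selection).
#' @param seed global seed.
#' @param generator named list of overrides passed to [generator_config()].
#' @param vocab named list of overrides for [build_vocabulary()]; the
#'   pipeline default uses word 1--2-grams without character n-grams and a
#'   document-frequency floor of 50, sized for the 50k-call synthetic
#'   cohort (the planted markers sit well above the floor while noise
#'   bigrams fall below it).
#' @param features_binary encode presence (`TRUE`, the pipeline default)
#'   rather than counts; presence features stop common-background counts
#'   from acting as a document-length proxy at extreme class imbalance.
#' @param mlp an [mlp_config()]; the pipeline default is a single
#'   32-unit hidden layer, a size matched to the synthetic vocabulary.
#' @param n_folds training folds (default 5).
#' @param validation_fraction held-out validation share (default 0.1).
#' @param ref_sens,ref_ppv call-taker reference operating point used for
#'   calibration (defaults 0.527 / 0.171).
#' @param include_emergency_line if `FALSE`, drop the emergency-line
#'   training data (the ablation arm).
#' @param n_perm permutations for significance tests (default 10000).
#' @param n_boot bootstrap replicates for CIs (default 1000).
#' @param occlusion_k length of the top-word lists (default 30).
#' @param occlusion_max_negative cap on the number of predicted-non-stroke
#'   documents scanned for the negative word list (they are orders of
#'   magnitude more numerous than positive predictions; a deterministic
#'   subsample keeps the scan tractable).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_calls = 50000L, n_runs = 11L, seed = 1L,
                            generator = list(),
                            vocab = list(word_n = c(1L, 2L), char_n = NULL,
                                         min_doc_freq = 50L,
                                         max_features = 50000L),
                            features_binary = TRUE,
                            mlp = mlp_config(hidden_sizes = 32L,
                                             dropout = 0,
                                             learning_rate = 0.01,
                                             batch_size = 1024L,
                                             max_epochs = 30L,
                                             patience = 6L, l2 = 1e-3),
                            n_folds = 5L, validation_fraction = 0.1,
                            ref_sens = 0.527, ref_ppv = 0.171,
                            include_emergency_line = TRUE,
                            n_perm = 10000L, n_boot = 1000L,
                            occlusion_k = 30L,
                            occlusion_max_negative = 200L) {
  structure(list(
    n_calls = as.integer(n_calls), n_runs = as.integer(n_runs),
    seed = as.integer(seed), generator = generator, vocab = vocab,
    features_binary = features_binary,
    mlp = mlp, n_folds = as.integer(n_folds),
    validation_fraction = validation_fraction,
    ref_sens = ref_sens, ref_ppv = ref_ppv,
    include_emergency_line = include_emergency_line,
    n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
    occlusion_k = as.integer(occlusion_k),
    occlusion_max_negative = as.integer(occlusion_max_negative)),
    class = "pipeline_config")
}

# cheap deterministic fingerprint of a config (no external hashing deps)
config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "mlp")]), collapse = "")
  txt <- paste0(txt, paste(deparse(unclass(config$mlp)), collapse = ""))
  sprintf("%08x", derive_seed(1L, txt))
}

#' Run the full synthetic study end to end
#'
#' Executes generate -> link -> split -> featurize -> train (n_runs seeded
#' runs of the five-member ensemble) -> calibrate -> evaluate -> occlude,
#' and optionally writes `results.json`, `curves.csv`, `occlusion.csv` and
#' `manifest.json` to `out_dir`. The result is a deterministic function of
#' `config`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param verbose print per-stage progress.
#' @return (invisibly when writing) a results bundle: see Details in the
#'   package vignette; notable elements are `metrics_model`,
#'   `metrics_calltaker`, `tests` (permutation results), `ci` (bootstrap
#'   CIs), `occlusion` (top word tables and indicator recovery), `subsets`,
#'   `median_run`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  say <- function(fmt, ...) if (verbose) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
  stage_seed <- function(stage) derive_seed(config$seed, stage)

  ## --- generate ------------------------------------------------------
  say("generating cohort of %d calls", config$n_calls)
  gen_args <- modifyList(list(n_calls = config$n_calls,
                              seed = stage_seed("generate")),
                         config$generator)
  gcfg <- do.call(generator_config, gen_args)
  cohort <- generate_cohort(gcfg)

  ## --- link + split --------------------------------------------------
  say("linking registry and splitting")
  linked <- link_cohort(cohort$calls, cohort$registry)
  test_year <- max(gcfg$years)
  subset <- split_dataset(linked, test_year, n_folds = config$n_folds,
                          validation_fraction = config$validation_fraction,
                          seed = stage_seed("split"))
  linked$subset <- subset

  ## --- featurize -----------------------------------------------------
  train_mask <- grepl("^train_fold_", subset) |
    (config$include_emergency_line & subset == "train_emergency")
  vocab_args <- modifyList(
    list(docs = cohort$transcripts[linked$call_id[train_mask]]),
    config$vocab)
  say("building vocabulary on %d training transcripts", sum(train_mask))
  vocab <- do.call(build_vocabulary, vocab_args)
  say("vectorizing %d transcripts (%d features)",
      length(cohort$transcripts), nrow(vocab$table))
  X <- vectorize_corpus(cohort$transcripts[linked$call_id], vocab,
                        binary = isTRUE(config$features_binary))
  y <- as.numeric(linked$ground_truth)

  take <- function(which_subset) {
    idx <- which(subset == which_subset)
    list(X = X[idx, , drop = FALSE], y = y[idx], idx = idx)
  }
  folds <- lapply(seq_len(config$n_folds),
                  function(k) take(sprintf("train_fold_%d", k)))
  extra <- if (config$include_emergency_line) take("train_emergency")
           else NULL
  val <- take("validation")
  test <- take("test")

  ## --- train + calibrate, n_runs seeded repetitions ------------------
  models <- vector("list", config$n_runs)
  thresholds <- vector("list", config$n_runs)
  val_f1 <- numeric(config$n_runs)
  pred_test <- matrix(0, length(test$y), config$n_runs)
  test_scores <- matrix(0, length(test$y), config$n_runs)
  for (r in seq_len(config$n_runs)) {
    say("training run %d/%d", r, config$n_runs)
    cfg_r <- config$mlp
    cfg_r$seed <- stage_seed(paste0("run", r))
    models[[r]] <- train_ensemble(folds, extra, cfg_r)
    thresholds[[r]] <- calibrate_ensemble(models[[r]], val$X, val$y,
                                          config$ref_sens, config$ref_ppv)
    val_scores <- ensemble_score(ensemble_member_logits(models[[r]], val$X),
                                 thresholds[[r]])
    val_f1[r] <- f1_at_threshold(val_scores, val$y)
    sc <- ensemble_score(ensemble_member_logits(models[[r]], test$X),
                         thresholds[[r]])
    test_scores[, r] <- sc
    pred_test[, r] <- as.numeric(sc >= 0.5)
  }

  ## --- evaluate ------------------------------------------------------
  say("evaluating")
  ct_pred <- as.numeric(linked$calltaker_positive[test$idx])
  metrics_model <- aggregate_runs(pred_test, test$y)
  metrics_calltaker <- compute_metrics(confusion_counts(ct_pred == 1,
                                                        test$y == 1))
  tests <- list(
    sensitivity = paired_permutation_test(
      pred_test, ct_pred, test$y, metric = "sensitivity",
      n_perm = config$n_perm, seed = stage_seed("perm_sens")),
    ppv = paired_permutation_test(
      pred_test, ct_pred, test$y, metric = "ppv",
      n_perm = config$n_perm, seed = stage_seed("perm_ppv")),
    f1 = paired_permutation_test(
      pred_test, ct_pred, test$y, metric = "f1",
      n_perm = config$n_perm, seed = stage_seed("perm_f1"))
  )
  ci <- lapply(setNames(nm = c("f1", "sensitivity", "ppv", "for_", "fpr")),
               function(m) {
                 bootstrap_ci(pred_test, test$y, metric = m,
                              n_boot = config$n_boot,
                              seed = stage_seed(paste0("boot_", m)))
               })

  ## --- occlusion on the median-F1 run --------------------------------
  say("occlusion analysis")
  ## odd run counts (the standard 11) use the order-statistic median; for
  ## even counts (smoke tests) the pipeline falls back to the lower median
  med <- if (config$n_runs %% 2 == 1) {
    select_median_model(models, val_f1)
  } else {
    lower_med <- sort(val_f1)[config$n_runs / 2]
    idx <- which(val_f1 == lower_med)[1]
    list(model = models[[idx]], index = idx, f1 = val_f1[idx])
  }
  med_pred <- pred_test[, med$index] == 1
  test_ids <- linked$call_id[test$idx]
  pos_docs <- cohort$transcripts[test_ids[med_pred]]
  neg_ids <- test_ids[!med_pred]
  if (length(neg_ids) > config$occlusion_max_negative) {
    neg_ids <- with_seed(stage_seed("occl_sample"),
                         sample(neg_ids, config$occlusion_max_negative))
  }
  neg_docs <- cohort$transcripts[neg_ids]
  occl <- list()
  if (length(pos_docs) > 0) {
    rep_pos <- occlusion_report(med$model, vocab, pos_docs,
                                group = "stroke_predictions")
    occl$positive <- top_words(rep_pos, config$occlusion_k, "positive")
    occl$D_positive <- rep_pos$D
  }
  if (length(neg_docs) > 0) {
    rep_neg <- occlusion_report(med$model, vocab, neg_docs,
                                group = "non_stroke_predictions")
    occl$negative <- top_words(rep_neg, config$occlusion_k, "negative")
    occl$D_negative <- rep_neg$D
  }
  occl$indicator_recovery <- if (!is.null(occl$positive)) {
    sum(gcfg$indicator_words %in% occl$positive$word)
  } else 0L

  curves <- roc_pr_points(test_scores[, med$index], test$y == 1)

  bundle <- list(
    config = config, generator_config = gcfg,
    subsets = table(subset),
    vocab_size = nrow(vocab$table),
    n_test = length(test$y), n_test_positive = sum(test$y),
    metrics_model = metrics_model, metrics_calltaker = metrics_calltaker,
    tests = tests, ci = ci,
    val_f1 = val_f1, median_run = med$index,
    occlusion = occl, curves = curves,
    pred_test = pred_test, calltaker_pred = ct_pred, test_labels = test$y,
    linked = linked, vocab = vocab, models = models,
    thresholds = thresholds
  )

  if (!is.null(out_dir)) {
    write_pipeline_outputs(bundle, out_dir)
    return(invisible(bundle))
  }
  bundle
}

# results.json / curves.csv / occlusion.csv / manifest.json
write_pipeline_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mm <- bundle$metrics_model
  mc <- bundle$metrics_calltaker
  results <- list(
    n_test = bundle$n_test,
    n_test_positive = bundle$n_test_positive,
    model = c(
      as.list(mm$mean),
      list(counts = as.list(mm$counts), n_runs = mm$n_runs,
           ci = lapply(bundle$ci, function(x)
             list(low = x$ci_low, high = x$ci_high)))),
    calltaker = list(f1 = mc$f1, sensitivity = mc$sensitivity, ppv = mc$ppv,
                     for_ = mc$for_, fpr = mc$fpr,
                     counts = as.list(mc$counts)),
    p_values = lapply(bundle$tests, function(t)
      list(metric = t$metric, observed = t$observed_stat, p = t$p_value)),
    median_run = bundle$median_run,
    indicator_recovery = bundle$occlusion$indicator_recovery,
    occlusion_D = list(positive = bundle$occlusion$D_positive,
                       negative = bundle$occlusion$D_negative)
  )
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  write.csv(bundle$curves, file.path(out_dir, "curves.csv"),
            row.names = FALSE)
  occ <- rbind(
    if (!is.null(bundle$occlusion$positive))
      cbind(bundle$occlusion$positive, group = "stroke_predictions"),
    if (!is.null(bundle$occlusion$negative))
      cbind(bundle$occlusion$negative, group = "non_stroke_predictions"))
  if (!is.null(occ)) {
    write.csv(occ, file.path(out_dir, "occlusion.csv"), row.names = FALSE)
  }
  manifest <- list(
    config_hash = config_hash(bundle$config),
    global_seed = bundle$config$seed,
    n_calls = bundle$config$n_calls,
    n_runs = bundle$config$n_runs,
    include_emergency_line = bundle$config$include_emergency_line,
    training_inputs = names(bundle$subsets)[
      grepl("^train", names(bundle$subsets)) &
        (bundle$config$include_emergency_line |
           names(bundle$subsets) != "train_emergency")],
    stage_seeds = lapply(
      setNames(nm = c("generate", "split", paste0(
        "run", seq_len(bundle$config$n_runs)))),
      function(s) derive_seed(bundle$config$seed, s))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
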