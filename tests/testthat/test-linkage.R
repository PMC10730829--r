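mk_call <- function(pid = "P1", start = as.POSIXct("2021-03-01 12:00:00",
                                                   tz = "UTC")) {
  data.frame(call_id = "C1", patient_id = pid, call_start = start,
             stringsAsFactors = FALSE)
}
mk_entry <- function(pid = "P1", offset_h = 0, type = "ischaemic") {
  data.frame(patient_id = pid,
             onset_time = as.POSIXct("2021-03-01 12:00:00", tz = "UTC") +
               offset_h * 3600,
             stroke_type = type, stringsAsFactors = FALSE)
}

test_that("ground-truth window labelling matches the -72h/+24h rule", {
  call <- mk_call()
  # zero offset inside the window
  expect_true(ground_truth_label(call, mk_entry(offset_h = 0))$positive)
  # one hour beyond the lower edge is out
  expect_false(ground_truth_label(call, mk_entry(offset_h = -73))$positive)
  # closed endpoints: exactly -72h and +24h are in
  expect_true(ground_truth_label(call, mk_entry(offset_h = -72))$positive)
  expect_true(ground_truth_label(call, mk_entry(offset_h = 24))$positive)
  expect_false(ground_truth_label(call, mk_entry(offset_h = 25))$positive)
  # subarachnoid haemorrhage matches are excluded
  sah <- mk_entry(offset_h = 0, type = "SAH")
  res <- ground_truth_label(call, sah)
  expect_false(res$positive)
  expect_null(res$entry)
  # ... but a SAH entry does not mask a qualifying non-SAH entry
  both <- rbind(sah, mk_entry(offset_h = -5))
  res <- ground_truth_label(call, both)
  expect_true(res$positive)
  expect_equal(res$entry$stroke_type, "ischaemic")
  # nearest-onset tie rule among several qualifying entries
  multi <- rbind(mk_entry(offset_h = -40), mk_entry(offset_h = 2))
  expect_equal(as.numeric(difftime(
    ground_truth_label(call, multi)$entry$onset_time, call$call_start,
    units = "hours")), 2)
  # a missing patient id warns and labels negative
  expect_warning(res <- ground_truth_label(mk_call(pid = NA), mk_entry()),
                 "patient_id")
  expect_false(res$positive)
})

test_that("call-taker label requires category AND appropriate dispatch", {
  expect_true(calltaker_label(TRUE, TRUE))
  expect_false(calltaker_label(TRUE, FALSE))
  expect_false(calltaker_label(FALSE, TRUE))
  expect_false(calltaker_label(FALSE, FALSE))
})

test_that("vectorised linkage agrees with a brute-force scan", {
  co <- generate_cohort(generator_config(
    2000, stroke_prevalence = 0.05, onset_outside_fraction = 0.3,
    sah_fraction = 0.3, seed = 13L))
  linked <- link_cohort(co$calls, co$registry)
  # independent brute force over all (call, entry) pairs
  brute <- logical(nrow(co$calls))
  for (i in seq_len(nrow(co$calls))) {
    pos <- FALSE
    for (j in seq_len(nrow(co$registry))) {
      if (co$registry$patient_id[j] == co$calls$patient_id[i] &&
          co$registry$stroke_type[j] != "SAH") {
        off <- as.numeric(difftime(co$registry$onset_time[j],
                                   co$calls$call_start[i], units = "hours"))
        if (off >= -72 && off <= 24) pos <- TRUE
      }
    }
    brute[i] <- pos
  }
  expect_identical(linked$ground_truth, brute)
})

test_that("dataset splitting partitions calls and stratifies prevalence", {
  co <- generate_cohort(generator_config(8000, stroke_prevalence = 0.05,
                                         seed = 17L))
  linked <- link_cohort(co$calls, co$registry)
  subset <- split_dataset(linked, test_year = 2021, seed = 3L)
  year <- as.integer(format(linked$call_start, "%Y"))

  # partition: every call in exactly one subset
  expect_false(anyNA(subset))
  expect_setequal(unique(subset),
                  intersect(c(sprintf("train_fold_%d", 1:5), "validation",
                              "test", "test_no_category", "train_emergency",
                              "excluded"), unique(subset)))

  # emergency calls never outside training; test-year ones are discarded
  emerg <- linked$line == "emergency"
  expect_true(all(subset[emerg & year == 2021] == "excluded"))
  expect_true(all(subset[emerg & year < 2021] == "train_emergency"))

  # helpline test-year calls split on category presence
  has_cat <- !is.na(linked$diagnostic_category)
  hl21 <- !emerg & year == 2021
  expect_true(all(subset[hl21 & has_cat] == "test"))
  expect_true(all(subset[hl21 & !has_cat] == "test_no_category"))

  # calls without a category never reach validation or test
  expect_true(all(has_cat[subset %in% c("validation", "test")]))

  # per-fold ground-truth prevalence within one call of the pooled value
  fold_pos <- tapply(linked$ground_truth, subset, sum)[
    sprintf("train_fold_%d", 1:5)]
  fold_n <- table(subset)[sprintf("train_fold_%d", 1:5)]
  pooled <- sum(fold_pos) / sum(fold_n)
  expect_true(all(abs(fold_pos - pooled * fold_n) <= 1 + 1e-9))

  # reproducible under the same seed
  expect_identical(subset, split_dataset(linked, 2021, seed = 3L))
})

test_that("split sizes follow the validation fraction on a controlled fixture", {
  n <- 1000
  calls <- data.frame(
    call_id = sprintf("C%04d", 1:n),
    line = "helpline",
    call_start = as.POSIXct("2020-06-01", tz = "UTC") + seq_len(n) * 3600,
    diagnostic_category = "other",
    ground_truth = rep(c(TRUE, FALSE), c(100, 900)),
    stringsAsFactors = FALSE
  )
  subset <- split_dataset(calls, test_year = 2021,
                          validation_fraction = 0.1, seed = 9L)
  expect_equal(sum(subset == "validation"), 100)
  folds <- table(subset[grepl("fold", subset)])
  expect_true(all(folds == 180))
  # equal stroke mass across folds within rounding
  fold_pos <- tapply(calls$ground_truth, subset, sum)[
    sprintf("train_fold_%d", 1:5)]
  expect_true(max(fold_pos) - min(fold_pos) <= 1)
})

test_that("an undersized stratum is reported by name", {
  calls <- data.frame(
    call_id = sprintf("C%02d", 1:10),
    line = "helpline",
    call_start = as.POSIXct("2020-06-01", tz = "UTC") + 1:10,
    diagnostic_category = "other",
    ground_truth = rep(c(TRUE, FALSE), c(2, 8)),
    stringsAsFactors = FALSE
  )
  expect_error(split_dataset(calls, 2021, seed = 1L), "stratum.*TRUE")
})
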