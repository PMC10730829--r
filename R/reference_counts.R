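#' Published reference cohort counts
#'
#' Call counts from the published Copenhagen 2015--2021 study population
#' table that this package's synthetic generator emulates: one row per data
#' subset (emergency-line training, helpline training, validation, test, and
#' test-year calls without a registered diagnostic category), with total,
#' stroke and non-stroke call counts and the female/male/65+ breakdowns for
#' each. These printed counts serve two purposes: they set the generator's
#' default demographic mix, and they let simple cohort arithmetic (stroke
#' prevalence by year and age group, percentage shares) be recomputed exactly.
#'
#' @return A data.frame with columns `subset`, `line`, `n_calls`, `n_stroke`,
#'   `n_nonstroke`, and count columns `female_`, `male_`, `age65_` crossed
#'   with `all`/`stroke`/`nonstroke`.
#' @export
#' @examples
#' rc <- reference_cohort_counts()
#' # stroke prevalence among all test-year calls, in percent:
#' with(rc, 100 * sum(n_stroke[subset %in% c("test", "test_no_category")]) /
#'   sum(n_calls[subset %in% c("test", "test_no_category")]))
reference_cohort_counts <- function() {
  data.frame(
    subset = c("train_emergency", "train_helpline", "validation",
               "test", "test_no_category"),
    line = c("emergency", rep("helpline", 4)),
    n_calls = c(155696, 1391301, 155825, 344030, 231009),
    n_stroke = c(3899, 3471, 360, 757, 679),
    n_nonstroke = c(151797, 1387830, 155465, 343273, 230330),
    female_all = c(74640, 792783, 86959, 190974, 134324),
    male_all = c(79564, 596760, 68866, 153050, 96258),
    age65_all = c(72930, 335146, 30313, 65652, 81488),
    female_stroke = c(1784, 1654, 161, 349, 366),
    male_stroke = c(2115, 1815, 199, 408, 313),
    age65_stroke = c(2968, 2421, 250, 555, 567),
    female_nonstroke = c(72856, 791129, 86798, 190625, 133958),
    male_nonstroke = c(77449, 594945, 68667, 152642, 95945),
    age65_nonstroke = c(69962, 332725, 30063, 65097, 80921),
    stringsAsFactors = FALSE
  )
}

#' Stroke prevalence arithmetic on the reference cohort
#'
#' Recomputes, from the printed reference counts, the three prevalence
#' figures quoted for the test year: overall stroke prevalence among all
#' test-year calls, and prevalence within the 65+ and 18--64 age groups of
#' the primary test subset. All values are percentages.
#'
#' @param counts a data.frame as returned by [reference_cohort_counts()].
#' @return Named numeric vector with elements `test_year_pct`,
#'   `age65plus_pct`, `age18_64_pct`.
#' @export
reference_prevalence_summary <- function(counts = reference_cohort_counts()) {
  yr <- counts$subset %in% c("test", "test_no_category")
  test <- counts[counts$subset == "test", ]
  c(
    test_year_pct = 100 * sum(counts$n_stroke[yr]) / sum(counts$n_calls[yr]),
    age65plus_pct = 100 * test$age65_stroke / test$age65_all,
    age18_64_pct = 100 * (test$n_stroke - test$age65_stroke) /
      (test$n_calls - test$age65_all)
  )
}
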