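# exhaustive scan oracle: try every candidate threshold directly
oracle_thresholds <- function(scores, labels, ref_sens, ref_ppv) {
  cand <- sort(unique(c(scores, 1)))
  sens <- vapply(cand, function(t) {
    sum(scores >= t & labels) / sum(labels)
  }, numeric(1))
  ppv <- vapply(cand, function(t) {
    np <- sum(scores >= t)
    if (np == 0) NA_real_ else sum(scores >= t & labels) / np
  }, numeric(1))
  c(t_sens = max(cand[sens >= ref_sens]),
    t_ppv = min(cand[!is.na(ppv) & ppv >= ref_ppv]))
}

test_that("matching thresholds agree with an exhaustive scan oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60
    labels <- runif(n) < 0.3
    scores <- round(runif(n), 2)  # force plenty of ties
    if (!any(labels) || all(labels)) next
    for (refs in list(c(0.5, 0.2), c(0.8, 0.3), c(0.3, 0.5))) {
      exp_t <- suppressWarnings(
        tryCatch(oracle_thresholds(scores, labels, refs[1], refs[2]),
                 error = function(e) NULL))
      if (is.null(exp_t) || !is.finite(exp_t["t_ppv"])) next
      got <- find_matching_thresholds(scores, labels, refs[1], refs[2])
      expect_equal(got, exp_t)
    }
  }
})

test_that("matching thresholds honour the documented conventions", {
  scores <- c(rep(0.9, 10), rep(0.1, 30))
  labels <- rep(c(TRUE, FALSE), c(10, 30))
  # perfectly separating scores: both thresholds land on the positive mass
  tt <- find_matching_thresholds(scores, labels, 0.9, 0.9)
  expect_equal(unname(tt["t_sens"]), 0.9)
  expect_equal(unname(tt["t_ppv"]), 0.9)

  # ref_sens = 0 is satisfied by the empty positive call at threshold 1
  tt <- find_matching_thresholds(scores, labels, 0, 0.2)
  expect_equal(unname(tt["t_sens"]), 1)

  # ref_ppv equal to prevalence is met near threshold 0 on random scores
  set.seed(8)
  sc <- runif(500)
  lb <- runif(500) < 0.3
  tt <- find_matching_thresholds(sc, lb, 0.5, mean(lb) * 0.9)
  expect_lt(unname(tt["t_ppv"]), 0.05)

  # unattainable PPV errors with the maximum attainable value
  expect_error(
    find_matching_thresholds(c(0.6, 0.5, 0.4), c(FALSE, TRUE, FALSE),
                             0.5, 0.9),
    "maximum attainable PPV is 0.5")
  expect_error(find_matching_thresholds(c(0.2, 0.3), c(TRUE, TRUE), 1, 1),
               "positive and one negative")
})

test_that("the harmonic-mean threshold follows its closed form", {
  expect_equal(harmonic_threshold(0.2, 0.8), 0.32)
  expect_equal(harmonic_threshold(0.5, 1.0), 2 / 3)
  for (t in c(0.05, 0.3, 0.99)) expect_equal(harmonic_threshold(t, t), t)
  # the harmonic mean always lies between its arguments
  for (seed in 1:20) {
    set.seed(seed)
    ts <- runif(2, 0.01, 0.99)
    h <- harmonic_threshold(ts[1], ts[2])
    expect_gte(h, min(ts)); expect_lte(h, max(ts))
  }
  expect_error(harmonic_threshold(0, 0.5), "positive")
})

test_that("logit centring gives all members a shared 0.5 threshold", {
  tau <- c(0.1, 0.37, 0.5, 0.82, 0.93)
  # members exactly at their thresholds: score exactly 0.5
  expect_equal(ensemble_score(logit(tau), threshold_set(tau)), 0.5,
               tolerance = 1e-12)

  # single member: decision identical to thresholding that member at tau
  set.seed(6)
  z <- rnorm(200)
  sc <- ensemble_score(matrix(z, ncol = 1), threshold_set(0.3))
  expect_identical(sc >= 0.5, sigmoid(z) >= 0.3)

  # two members, z = (2, 0) at tau = 0.5: mean centred logit 1
  expect_equal(ensemble_score(c(2, 0), threshold_set(c(0.5, 0.5))),
               sigmoid(1), tolerance = 1e-12)
  expect_equal(sigmoid(1), 0.7311, tolerance = 1e-4)

  # monotonicity: raising any member logit never lowers the score
  set.seed(9)
  Z <- matrix(rnorm(50 * 3), 50, 3)
  tau <- c(0.2, 0.6, 0.9)
  s0 <- ensemble_score(Z, threshold_set(tau))
  for (k in 1:3) {
    Z2 <- Z
    Z2[, k] <- Z2[, k] + abs(rnorm(50))
    expect_true(all(ensemble_score(Z2, threshold_set(tau)) >= s0 - 1e-12))
  }

  expect_error(threshold_set(c(0.5, 1)), "inside \\(0,1\\)")
  expect_error(ensemble_score(c(1, 1), c(0.4, 0)), "inside \\(0,1\\)")
})

test_that("the centred ensemble dominates its members' ROC on shared signal", {
  # members observe the same latent signal plus independent noise; the
  # averaged centred logit suppresses the noise, so the ensemble ROC should
  # match or beat each member at matched FPR (up to sampling tolerance)
  set.seed(15)
  n <- 4000
  y <- runif(n) < 0.1
  latent <- ifelse(y, 1.5, -1.5)
  Z <- vapply(1:5, function(k) latent + rnorm(n, sd = 1.5), numeric(n))
  tau <- rep(0.5, 5)
  ens <- ensemble_score(Z, threshold_set(tau))
  auc_members <- vapply(1:5, function(k) auroc(sigmoid(Z[, k]), y),
                        numeric(1))
  expect_gte(auroc(ens, y), max(auc_members) - 0.01)
})

test_that("calibrated ensemble operates between its members' matched points", {
  # correlated member scores around a common signal
  set.seed(23)
  n <- 3000
  y <- runif(n) < 0.05
  latent <- ifelse(y, 2.5, -2.5) + rnorm(n)
  Z <- vapply(1:5, function(k) latent + rnorm(n, sd = 0.4), numeric(n))
  members <- lapply(1:5, function(k) linear_member(1))
  ens <- fake_ensemble(members)
  # calibrate directly from the member scores
  ref_sens <- 0.6; ref_ppv <- 0.3
  t_sens <- numeric(5); t_ppv <- numeric(5)
  for (k in 1:5) {
    tt <- find_matching_thresholds(sigmoid(Z[, k]), y, ref_sens, ref_ppv)
    t_sens[k] <- tt["t_sens"]; t_ppv[k] <- tt["t_ppv"]
  }
  ts <- threshold_set(mapply(harmonic_threshold, t_sens, t_ppv),
                      t_sens, t_ppv, ref_sens, ref_ppv)
  sc <- ensemble_score(Z, ts)
  ens_sens <- binary_metric(sc >= 0.5, y, "sensitivity")
  ens_ppv <- binary_metric(sc >= 0.5, y, "ppv")
  tol <- 0.02
  for (k in 1:5) {
    s_at <- function(t) binary_metric(sigmoid(Z[, k]) >= t, y, "sensitivity")
    p_at <- function(t) binary_metric(sigmoid(Z[, k]) >= t, y, "ppv")
    sens_lo <- min(s_at(ts$t_sens[k]), s_at(ts$t_ppv[k]))
    sens_hi <- max(s_at(ts$t_sens[k]), s_at(ts$t_ppv[k]))
    expect_gte(ens_sens, sens_lo - tol)
    expect_lte(ens_sens, sens_hi + tol)
    ppv_lo <- min(p_at(ts$t_sens[k]), p_at(ts$t_ppv[k]))
    ppv_hi <- max(p_at(ts$t_sens[k]), p_at(ts$t_ppv[k]))
    expect_gte(ens_ppv, ppv_lo - tol)
    expect_lte(ens_ppv, ppv_hi + tol)
  }
})

test_that("threshold sets serialize to JSON and back", {
  ts <- threshold_set(c(0.3, 0.5), c(0.6, 0.7), c(0.2, 0.4), 0.527, 0.171)
  path <- withr::local_tempfile(fileext = ".json")
  write_threshold_set(ts, path)
  ts2 <- read_threshold_set(path)
  expect_equal(ts2$tau, ts$tau)
  expect_equal(ts2$ref_sens, 0.527)
})
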