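separable_data <- function(n = 300, seed = 2) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  X <- matrix(rnorm(n * 2, sd = 0.3), n, 2) + cbind(2 * y - 1, 1 - 2 * y)
  list(X = X, y = y)
}

test_that("the MLP fits linearly separable data to F1 = 1", {
  d <- separable_data()
  cfg <- mlp_config(hidden_sizes = 8L, dropout = 0, learning_rate = 0.02,
                    batch_size = 64L, max_epochs = 60L, patience = 15L,
                    seed = 4L)
  m <- mlp_fit(d$X, d$y, d$X, d$y, cfg)
  expect_equal(f1_at_threshold(mlp_scores(m, d$X), d$y), 1)
})

test_that("training is deterministic and sigmoid-consistent", {
  d <- separable_data(120, seed = 5)
  cfg <- mlp_config(hidden_sizes = c(6L, 4L), dropout = 0.2,
                    learning_rate = 0.01, batch_size = 32L,
                    max_epochs = 10L, patience = 5L, seed = 9L)
  m1 <- mlp_fit(d$X, d$y, d$X, d$y, cfg)
  m2 <- mlp_fit(d$X, d$y, d$X, d$y, cfg)
  expect_identical(m1$stop_f1_history, m2$stop_f1_history)
  expect_identical(m1$W, m2$W)
  expect_lt(max(abs(sigmoid(mlp_logits(m1, d$X)) - mlp_scores(m1, d$X))),
            1e-12)
})

test_that("labels independent of features yield chance-level stop F1", {
  set.seed(31)
  n <- 400
  X <- matrix(rnorm(n * 5), n, 5)
  y <- rbinom(n, 1, 0.3)
  Xs <- matrix(rnorm(200 * 5), 200, 5)
  ys <- rbinom(200, 1, 0.3)
  m <- mlp_fit(X, y, Xs, ys, mlp_config(hidden_sizes = 8L, dropout = 0,
                                        learning_rate = 0.01,
                                        batch_size = 64L, max_epochs = 15L,
                                        patience = 15L, seed = 8L))
  pred <- mlp_scores(m, Xs) >= 0.5
  # Monte-Carlo permutation baseline: the model's stop-fold F1 must sit
  # inside the null distribution obtained by permuting the labels
  null_f1 <- replicate(400, {
    f1_at_threshold(as.numeric(pred), sample(ys))
  })
  obs <- f1_at_threshold(as.numeric(pred), ys)
  expect_gte(obs, quantile(null_f1, 0.005))
  expect_lte(obs, quantile(null_f1, 0.995))
})

test_that("the first optimisation step descends the numerical gradient", {
  set.seed(12)
  X <- matrix(rnorm(18), 6, 3)
  y <- c(1, 0, 1, 0, 1, 0)
  base <- mlp_config(hidden_sizes = 2L, dropout = 0, learning_rate = 1e-12,
                     batch_size = 6L, max_epochs = 1L, patience = 1L,
                     l2 = 0, seed = 3L)
  # with lr ~ 0 one epoch leaves the seeded initialisation untouched
  m0 <- mlp_fit(X, y, NULL, NULL, base)
  stepped <- base
  stepped$learning_rate <- 0.05
  m1 <- mlp_fit(X, y, NULL, NULL, stepped)
  # first Adam step is -lr * sign(gradient); compare against a central
  # finite difference of the binary cross-entropy at the initial weights
  loss_at <- function(W1) {
    model <- m0
    model$W[[1]] <- W1
    z <- mlp_logits(model, X)
    mean(-(y * log(sigmoid(z)) + (1 - y) * log(1 - sigmoid(z))))
  }
  eps <- 1e-6
  for (idx in list(c(1, 1), c(2, 2), c(3, 1))) {
    Wp <- m0$W[[1]]; Wm <- m0$W[[1]]
    Wp[idx[1], idx[2]] <- Wp[idx[1], idx[2]] + eps
    Wm[idx[1], idx[2]] <- Wm[idx[1], idx[2]] - eps
    g_num <- (loss_at(Wp) - loss_at(Wm)) / (2 * eps)
    if (abs(g_num) > 1e-4) {
      step <- m1$W[[1]][idx[1], idx[2]] - m0$W[[1]][idx[1], idx[2]]
      expect_equal(sign(step), -sign(g_num))
      expect_equal(abs(step), 0.05, tolerance = 0.01)
    }
  }
})

test_that("degenerate single-class training data is rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(mlp_fit(X, rep(1, 10)), "single class")
})

test_that("the ensemble rotates stop folds over independent members", {
  set.seed(44)
  folds <- lapply(1:5, function(k) {
    d <- separable_data(60, seed = k)
    list(X = d$X, y = d$y)
  })
  cfg <- mlp_config(hidden_sizes = 4L, dropout = 0, learning_rate = 0.02,
                    batch_size = 32L, max_epochs = 5L, patience = 3L,
                    seed = 7L)
  ens <- train_ensemble(folds, extra_train = NULL, config = cfg)
  expect_length(ens$members, 5)
  expect_setequal(ens$fold_assignment, 1:5)

  # no shared state: retraining one member in isolation reproduces it
  cfg_k <- cfg
  cfg_k$seed <- strokecall:::derive_seed(cfg$seed, "member3")
  solo <- train_member(folds[-3], folds[[3]], NULL, cfg_k)
  expect_identical(solo$W, ens$members[[3]]$W)

  # extra training data changes members but not the fold rotation
  extra <- {
    d <- separable_data(40, seed = 99)
    list(X = d$X, y = d$y)
  }
  ens2 <- train_ensemble(folds, extra_train = extra, config = cfg)
  expect_setequal(ens2$fold_assignment, 1:5)
  expect_false(identical(ens2$members[[1]]$W, ens$members[[1]]$W))
})

test_that("grid search maximises calibrated validation F1 with stable ties", {
  folds <- lapply(1:5, function(k) {
    d <- separable_data(60, seed = k + 10)
    list(X = d$X, y = d$y)
  })
  val <- {
    d <- separable_data(80, seed = 77)
    list(X = d$X, y = d$y)
  }
  good <- mlp_config(hidden_sizes = 4L, dropout = 0, learning_rate = 0.02,
                     batch_size = 32L, max_epochs = 8L, patience = 4L,
                     seed = 7L)
  # singleton grid returns that configuration
  g1 <- grid_search(list(good), folds, NULL, val,
                    ref_sens = 0.5, ref_ppv = 0.5)
  expect_equal(g1$index, 1)

  # a near-zero learning rate loses to the working configuration
  frozen <- good
  frozen$learning_rate <- 1e-9
  g2 <- grid_search(list(frozen, good), folds, NULL, val,
                    ref_sens = 0.5, ref_ppv = 0.5)
  expect_equal(g2$index, 2)

  # reported F1 equals an independent recomputation on the validation set
  sc <- ensemble_score(ensemble_member_logits(g2$model, val$X),
                       g2$thresholds)
  expect_equal(g2$f1, f1_at_threshold(sc, val$y))
})
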