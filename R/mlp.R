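#' Multi-layer perceptron configuration
#'
#' Hyperparameters for one classifier in the ensemble. The network is a
#' stack of fully connected layers ending in a single scalar output passed
#' through a sigmoid; training minimises binary cross-entropy with the Adam
#' optimiser and stops early when the stop-fold F1-score (at threshold 0.5)
#' fails to improve for `patience` consecutive epochs.
#'
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param activation `"relu"` or `"tanh"`.
#' @param dropout dropout probability on hidden activations during training.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience epochs without stop-fold F1 improvement before stopping.
#' @param l2 L2 weight-decay coefficient.
#' @param pos_weight multiplier on the positive-class loss term (1 = no
#'   reweighting, the default).
#' @param seed integer seed controlling initialisation, shuffling, dropout.
#' @return object of class `mlp_config`.
#' @export
mlp_config <- function(hidden_sizes = c(256L, 256L), activation = "relu",
                       dropout = 0.3, learning_rate = 1e-3,
                       batch_size = 256L, max_epochs = 50L, patience = 5L,
                       l2 = 0, pos_weight = 1, seed = 1L) {
  stopifnot(activation %in% c("relu", "tanh"),
            dropout >= 0, dropout < 1, learning_rate > 0,
            batch_size >= 1, max_epochs >= 1, patience >= 1, l2 >= 0,
            pos_weight > 0)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 activation = activation, dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), l2 = l2,
                 pos_weight = pos_weight, seed = as.integer(seed)),
            class = "mlp_config")
}

# F1 at a fixed threshold from scores; 0 when undefined (no positives
# predicted or present) so early stopping has a total order
f1_at_threshold <- function(scores, y, threshold = 0.5) {
  pred <- scores >= threshold
  tp <- sum(pred & y == 1)
  denom <- 2 * tp + sum(pred & y == 0) + sum(!pred & y == 1)
  if (denom == 0) 0 else 2 * tp / denom
}

act_fun <- function(z, activation) {
  if (activation == "relu") pmax(z, 0) else tanh(z)
}
act_grad <- function(z, a, activation) {
  if (activation == "relu") (z > 0) * 1 else 1 - a^2
}

mlp_forward_train <- function(W, b, X, activation, dropout) {
  L <- length(W)
  A <- X
  Zs <- vector("list", L); As <- vector("list", L); masks <- vector("list", L)
  for (l in seq_len(L)) {
    Z <- as.matrix(A %*% W[[l]])
    Z <- Z + rep(b[[l]], each = nrow(Z))
    if (l < L) {
      Aout <- act_fun(Z, activation)
      if (dropout > 0) {
        m <- matrix((runif(length(Aout)) >= dropout) / (1 - dropout),
                    nrow(Aout), ncol(Aout))
        Aout <- Aout * m
        masks[[l]] <- m
      }
    } else {
      Aout <- Z
    }
    Zs[[l]] <- Z; As[[l]] <- Aout
    A <- Aout
  }
  list(Zs = Zs, As = As, masks = masks)
}

#' Train a multi-layer perceptron on sparse bag-of-words features
#'
#' Minimises (optionally class-weighted) binary cross-entropy with Adam.
#' Rows are shuffled once and partitioned into fixed minibatches; each
#' epoch sweeps the partition. When a stop set is supplied, the stop-fold
#' F1-score at threshold 0.5 is evaluated after every epoch, the best-F1
#' weights are checkpointed (an epoch tying the current best refreshes the
#' checkpoint, so long plateaus keep the most-converged weights), and
#' training halts once F1 has stayed strictly below the best for
#' `patience` consecutive evaluations. Fully deterministic given
#' `config$seed`.
#'
#' @param X training features, a `dgCMatrix` or dense matrix (rows = calls).
#' @param y numeric/logical labels (0/1).
#' @param X_stop,y_stop early-stopping fold (optional; without it training
#'   runs for `max_epochs`).
#' @param config an [mlp_config()].
#' @return object of class `strokecall_mlp` with elements `W`, `b`,
#'   `config`, `stop_f1_history`, `best_epoch`, `best_f1`.
#' @export
mlp_fit <- function(X, y, X_stop = NULL, y_stop = NULL, config = mlp_config()) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    stop("degenerate training data: labels contain a single class")
  }
  stopifnot(nrow(X) == length(y))
  with_seed(config$seed, {
    sizes <- c(ncol(X), config$hidden_sizes, 1L)
    L <- length(sizes) - 1L
    W <- vector("list", L); b <- vector("list", L)
    mW <- vector("list", L); vW <- vector("list", L)
    mB <- vector("list", L); vB <- vector("list", L)
    for (l in seq_len(L)) {
      sd_init <- sqrt(2 / sizes[l])
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], 0, sd_init),
                       sizes[l], sizes[l + 1])
      b[[l]] <- numeric(sizes[l + 1])
      mW[[l]] <- W[[l]] * 0; vW[[l]] <- W[[l]] * 0
      mB[[l]] <- b[[l]] * 0; vB[[l]] <- b[[l]] * 0
    }
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0

    n <- nrow(X)
    perm <- sample.int(n)
    n_batch <- max(1L, ceiling(n / config$batch_size))
    batch_of <- rep_len(seq_len(n_batch), n)
    batches <- lapply(seq_len(n_batch), function(k) {
      idx <- perm[batch_of == k]
      list(X = X[idx, , drop = FALSE], y = y[idx])
    })

    best <- list(W = W, b = b, f1 = -Inf, epoch = 0L)
    history <- numeric(0)
    stall <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      for (bt in batches) {
        fw <- mlp_forward_train(W, b, bt$X, config$activation, config$dropout)
        z <- drop(fw$As[[L]])
        wgt <- ifelse(bt$y == 1, config$pos_weight, 1)
        delta <- matrix(wgt * (sigmoid(z) - bt$y) / length(bt$y), ncol = 1)
        gW <- vector("list", L); gB <- vector("list", L)
        for (l in rev(seq_len(L))) {
          A_prev <- if (l == 1) bt$X else fw$As[[l - 1]]
          gW[[l]] <- as.matrix(Matrix::crossprod(A_prev, delta)) +
            config$l2 * W[[l]]
          gB[[l]] <- colSums(delta)
          if (l > 1) {
            delta <- delta %*% t(W[[l]])
            if (!is.null(fw$masks[[l - 1]])) delta <- delta * fw$masks[[l - 1]]
            delta <- delta * act_grad(fw$Zs[[l - 1]], fw$As[[l - 1]],
                                      config$activation)
          }
        }
        t_step <- t_step + 1
        corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
        for (l in seq_len(L)) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
          W[[l]] <- W[[l]] - config$learning_rate * (mW[[l]] / corr1) /
            (sqrt(vW[[l]] / corr2) + eps)
          mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gB[[l]]
          vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gB[[l]]^2
          b[[l]] <- b[[l]] - config$learning_rate * (mB[[l]] / corr1) /
            (sqrt(vB[[l]] / corr2) + eps)
        }
      }
      if (!is.null(X_stop)) {
        f1 <- f1_at_threshold(sigmoid(mlp_logits_raw(W, b, X_stop,
                                                     config$activation)),
                              as.numeric(y_stop))
        history <- c(history, f1)
        # ">=": an epoch matching the best F1 refreshes the checkpoint, so a
        # long plateau keeps the most-converged weights; only a drop below
        # the best counts towards patience
        if (f1 >= best$f1) {
          best <- list(W = lapply(W, identity), b = lapply(b, identity),
                       f1 = f1, epoch = epoch)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= config$patience) break
        }
      } else {
        best <- list(W = W, b = b, f1 = NA_real_, epoch = epoch)
      }
    }
    structure(list(W = best$W, b = best$b, config = config,
                   stop_f1_history = history, best_epoch = best$epoch,
                   best_f1 = best$f1, n_features = ncol(X)),
              class = "strokecall_mlp")
  })
}

mlp_logits_raw <- function(W, b, X, activation) {
  A <- X
  L <- length(W)
  for (l in seq_len(L)) {
    Z <- as.matrix(A %*% W[[l]])
    Z <- Z + rep(b[[l]], each = nrow(Z))
    A <- if (l < L) act_fun(Z, activation) else Z
  }
  drop(A)
}

#' Logits and scores of a trained MLP
#'
#' @param model a `strokecall_mlp`.
#' @param X feature matrix (sparse or dense), or a single numeric feature
#'   vector.
#' @return `mlp_logits()` returns the raw pre-sigmoid outputs;
#'   `mlp_scores()` their sigmoid.
#' @export
mlp_logits <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  mlp_logits_raw(model$W, model$b, X, model$config$activation)
}

#' @rdname mlp_logits
#' @export
mlp_scores <- function(model, X) sigmoid(mlp_logits(model, X))

#' @export
print.strokecall_mlp <- function(x, ...) {
  cat(sprintf("<strokecall_mlp> %d -> %s -> 1; best stop-fold F1 %.3f (epoch %d)\n",
              x$n_features,
              paste(x$config$hidden_sizes, collapse = " -> "),
              x$best_f1, x$best_epoch))
  invisible(x)
}
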