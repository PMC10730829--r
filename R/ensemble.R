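#' Train one ensemble member
#'
#' Trains an MLP on the concatenation of the supplied training folds plus
#' optional extra training data (the emergency-line calls in the full
#' pipeline), early-stopping on the held-out stop fold's F1-score. The stop
#' fold must be disjoint from the training folds.
#'
#' @param train list of fold datasets, each `list(X =, y =)`.
#' @param stop_fold the early-stopping fold, `list(X =, y =)`.
#' @param extra_train optional additional training dataset `list(X =, y =)`.
#' @param config an [mlp_config()].
#' @return a `strokecall_mlp`.
#' @export
train_member <- function(train, stop_fold, extra_train = NULL,
                         config = mlp_config()) {
  Xs <- lapply(train, `[[`, "X")
  ys <- lapply(train, `[[`, "y")
  if (!is.null(extra_train)) {
    Xs <- c(Xs, list(extra_train$X))
    ys <- c(ys, list(extra_train$y))
  }
  X <- do.call(rbind, Xs)
  y <- as.numeric(unlist(ys, use.names = FALSE))
  mlp_fit(X, y, stop_fold$X, as.numeric(stop_fold$y), config)
}

#' Train the five-member MLP ensemble
#'
#' One member per fold: member *k* uses fold *k* for early stopping and
#' trains on the remaining folds (plus `extra_train`, if given). Members
#' are identical in architecture and differ only in their fold rotation and
#' seed (`config$seed + k`), and share no state.
#'
#' @param folds list of `n` fold datasets `list(X =, y =)` (default usage:
#'   5 folds).
#' @param extra_train optional dataset appended to every member's training
#'   data; omit to reproduce the "without emergency-line data" ablation.
#' @param config an [mlp_config()]; per-member seeds are derived from
#'   `config$seed`.
#' @return object of class `strokecall_ensemble` with `members` (list of
#'   `strokecall_mlp`) and `fold_assignment` (stop fold of each member).
#' @export
train_ensemble <- function(folds, extra_train = NULL, config = mlp_config()) {
  n_folds <- length(folds)
  members <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    cfg_k <- config
    cfg_k$seed <- derive_seed(config$seed, paste0("member", k))
    members[[k]] <- train_member(folds[-k], folds[[k]], extra_train, cfg_k)
  }
  structure(list(members = members, fold_assignment = seq_len(n_folds),
                 N = n_folds, config = config),
            class = "strokecall_ensemble")
}

#' Per-member logits of an ensemble
#'
#' @param ensemble a `strokecall_ensemble`.
#' @param X feature matrix.
#' @return numeric matrix, one column per member.
#' @export
ensemble_member_logits <- function(ensemble, X) {
  vapply(ensemble$members, function(m) mlp_logits(m, X),
         numeric(if (is.null(dim(X))) 1L else nrow(X)))
}

#' @export
print.strokecall_ensemble <- function(x, ...) {
  cat(sprintf("<strokecall_ensemble> %d members, stop folds %s\n", x$N,
              paste(x$fold_assignment, collapse = ",")))
  invisible(x)
}

#' Hyperparameter grid search over calibrated ensembles
#'
#' Trains one ensemble per configuration, calibrates its thresholds against
#' the call-taker reference operating point on the validation set, and
#' returns the configuration whose calibrated ensemble attains the best
#' validation F1-score at the shared 0.5 threshold. Ties are broken by grid
#' order.
#'
#' @param grid list of [mlp_config()] objects.
#' @param folds,extra_train as in [train_ensemble()].
#' @param val validation dataset `list(X =, y =)`.
#' @param ref_sens,ref_ppv call-taker reference sensitivity and PPV used for
#'   calibration.
#' @return list with `model`, `thresholds`, `f1`, `config`, `index`, and
#'   the per-configuration F1s `grid_f1`.
#' @export
grid_search <- function(grid, folds, extra_train = NULL, val,
                        ref_sens = 0.527, ref_ppv = 0.171) {
  stopifnot(length(grid) >= 1)
  best <- NULL
  grid_f1 <- numeric(length(grid))
  for (g in seq_along(grid)) {
    model <- train_ensemble(folds, extra_train, grid[[g]])
    thresholds <- calibrate_ensemble(model, val$X, val$y, ref_sens, ref_ppv)
    scores <- ensemble_score(ensemble_member_logits(model, val$X),
                             thresholds)
    f1 <- f1_at_threshold(scores, as.numeric(val$y))
    grid_f1[g] <- f1
    if (is.null(best) || f1 > best$f1) {
      best <- list(model = model, thresholds = thresholds, f1 = f1,
                   config = grid[[g]], index = g)
    }
  }
  best$grid_f1 <- grid_f1
  best
}
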