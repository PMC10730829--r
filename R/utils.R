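#' Logistic (sigmoid) function and its inverse
#'
#' `sigmoid()` maps a logit to (0,1); `logit()` is its inverse. Both are
#' vectorised and numerically guarded: `sigmoid()` is computed in a form
#' stable for large |x|, and `logit()` refuses values outside (0,1).
#'
#' @param x numeric vector.
#' @param p numeric vector of probabilities in (0,1).
#' @return numeric vector.
#' @export
sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out[is.na(x)] <- NA_real_
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' @rdname sigmoid
#' @export
logit <- function(p) {
  if (any(p <= 0 | p >= 1, na.rm = TRUE)) {
    stop("logit() requires probabilities strictly inside (0,1)")
  }
  log(p / (1 - p))
}

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stage label, keeping the
# result a valid 32-bit integer. Stable across platforms (no hashing libs).
derive_seed <- function(seed, stage) {
  codes <- utf8ToInt(as.character(stage))
  h <- as.double(seed %% 2147483647L)
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

stopifnot_fraction <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && all(!is.na(x)) &&
    if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) stop(sprintf("`%s` must be a fraction in %s", name,
                        if (open) "(0,1)" else "[0,1]"), call. = FALSE)
  invisible(x)
}
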