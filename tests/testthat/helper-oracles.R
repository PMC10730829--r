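# Independent oracle implementations used to cross-check the package's
# vectorised code paths. These deliberately use plain loops and naive
# enumeration, no sparsity shortcuts, and share no code with R/.

# enumerate all features of one token sequence the slow way
naive_doc_features <- function(tokens, word_n, char_n) {
  feats <- character(0)
  if (!is.null(word_n)) {
    for (n in word_n[1]:word_n[2]) {
      if (length(tokens) >= n) {
        for (i in seq_len(length(tokens) - n + 1)) {
          feats <- c(feats,
                     paste0(sprintf("word%d", n), "\r",
                            paste(tokens[i:(i + n - 1)], collapse = " ")))
        }
      }
    }
  }
  if (!is.null(char_n)) {
    for (tok in tokens) {
      padded <- paste0("_", tok, "_")
      for (n in char_n[1]:char_n[2]) {
        if (nchar(padded) >= n) {
          for (i in seq_len(nchar(padded) - n + 1)) {
            feats <- c(feats, paste0("char\r", substr(padded, i, i + n - 1)))
          }
        }
      }
    }
  }
  feats
}

# count vocabulary features in a document by linear search
naive_vectorize <- function(tokens, vocab) {
  feats <- naive_doc_features(tokens, vocab$word_n, vocab$char_n)
  keys <- paste0(vocab$table$type, "\r", vocab$table$feature)
  out <- numeric(length(keys))
  for (f in feats) {
    for (k in seq_along(keys)) {
      if (f == keys[k]) out[k] <- out[k] + 1
    }
  }
  out
}

# forward pass through an MLP with explicit loops over layers
naive_mlp_logit <- function(model, x) {
  a <- x
  L <- length(model$W)
  for (l in seq_len(L)) {
    z <- drop(t(model$W[[l]]) %*% a) + model$b[[l]]
    if (l < L) {
      a <- if (model$config$activation == "relu") pmax(z, 0) else tanh(z)
    } else {
      a <- z
    }
  }
  a
}

# build an untrained MLP with externally supplied (or random) weights; a
# valid strokecall_mlp for inference-only tests
fake_mlp <- function(n_features, hidden = c(4L), seed = 1L,
                     W = NULL, b = NULL, scale = 0.5) {
  cfg <- mlp_config(hidden_sizes = hidden, dropout = 0, seed = seed)
  sizes <- c(n_features, hidden, 1L)
  if (is.null(W)) {
    set.seed(seed)
    W <- lapply(seq_len(length(sizes) - 1), function(l) {
      matrix(rnorm(sizes[l] * sizes[l + 1], 0, scale), sizes[l], sizes[l + 1])
    })
    b <- lapply(seq_len(length(sizes) - 1),
                function(l) rnorm(sizes[l + 1], 0, scale))
  }
  structure(list(W = W, b = b, config = cfg, stop_f1_history = numeric(0),
                 best_epoch = 0L, best_f1 = NA_real_,
                 n_features = n_features),
            class = "strokecall_mlp")
}

# a linear single-output "MLP": logit = x . w + b
linear_member <- function(w, b = 0) {
  structure(list(W = list(matrix(w, ncol = 1)), b = list(b),
                 config = mlp_config(hidden_sizes = integer(0), dropout = 0),
                 stop_f1_history = numeric(0), best_epoch = 0L,
                 best_f1 = NA_real_, n_features = length(w)),
            class = "strokecall_mlp")
}

fake_ensemble <- function(members) {
  structure(list(members = members, fold_assignment = seq_along(members),
                 N = length(members), config = members[[1]]$config),
            class = "strokecall_ensemble")
}

# random token documents over a small lexicon, with marker words planted in
# a labelled subset
random_docs <- function(n_docs, lexicon = sprintf("t%02d", 1:15),
                        len_range = c(3, 10), seed = 1) {
  set.seed(seed)
  docs <- lapply(seq_len(n_docs), function(i) {
    sample(lexicon, sample(len_range[1]:len_range[2], 1), replace = TRUE)
  })
  names(docs) <- sprintf("d%03d", seq_len(n_docs))
  docs
}

# pipeline configuration for the 2,000-call smoke study: prevalence is
# raised to 5% so every stratum is populated at this size, and the
# vocabulary threshold is scaled down with the corpus
smoke_config <- function(seed, n_runs = 2L) {
  pipeline_config(
    n_calls = 2000L, n_runs = n_runs, seed = seed,
    generator = list(stroke_prevalence = 0.05),
    vocab = list(word_n = c(1L, 2L), char_n = NULL, min_doc_freq = 5L,
                 max_features = 20000L),
    mlp = mlp_config(hidden_sizes = 16L, dropout = 0, learning_rate = 0.01,
                     batch_size = 256L, max_epochs = 15L, patience = 4L,
                     l2 = 1e-3),
    n_perm = 200L, n_boot = 100L, occlusion_max_negative = 50L)
}
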