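#' Word impact score by occlusion
#'
#' Removes every instance of `word` from the transcript before
#' re-vectorisation (discarding all word and character n-grams that touch
#' it) and returns the mean, over ensemble members, of the logit change:
#' `i(d,w) = (1/N) * sum_n (z(n,d) - z(n,d,w))`. Impacts are computed on
#' raw member logits, not sigmoid scores: for documents scored close to 0
#' or 1 the sigmoid-scale difference is biased towards zero, while the
#' logit-scale difference is not. (The per-member threshold centring is a
#' constant shift and cancels in the difference.)
#'
#' @param ensemble a `strokecall_ensemble`.
#' @param vocab the fixed `strokecall_vocabulary`.
#' @param tokens transcript token vector.
#' @param word token to occlude.
#' @return numeric scalar; exactly 0 when `word` is absent.
#' @export
impact_score <- function(ensemble, vocab, tokens, word) {
  if (!word %in% tokens) return(0)
  v0 <- vectorize(tokens, vocab)
  v1 <- vectorize(occlude_word(tokens, word), vocab)
  X <- rbind(v0, v1)
  z <- ensemble_member_logits(ensemble, X)
  mean(z[1, ] - z[2, ])
}

#' Ranking score of a word from its per-document impacts
#'
#' Sum of signed squares, `r(w) = sum_d sgn(i(d,w)) * i(d,w)^2`: squaring
#' favours rare, high-impact words over common, low-impact ones.
#'
#' @param impacts numeric vector of impact values for one word (documents
#'   not containing the word contribute 0 and may be omitted).
#' @return numeric scalar.
#' @export
ranking_score <- function(impacts) {
  sum(sign(impacts) * impacts^2)
}

#' Occlusion report over a prediction group
#'
#' Computes impact scores for every candidate word in every document of a
#' prediction group (the model's predicted-stroke or predicted-non-stroke
#' calls) and aggregates them into per-word ranking scores and occurrence
#' counts. Candidate words default to the vocabulary's word unigrams;
#' occurrence counts `D_w` count the documents of the group containing the
#' word.
#'
#' @param ensemble a `strokecall_ensemble`.
#' @param vocab the fixed vocabulary.
#' @param docs list of token vectors (the prediction group).
#' @param group label stored in the report (e.g. `"stroke_predictions"`).
#' @param candidate_words words to occlude; default all word unigrams.
#' @return object of class `occlusion_report`: data.frame `per_word`
#'   (word, rank_score, occurrences, mean_impact, group), list
#'   `per_doc_impacts` (one named numeric vector per document), and `D`,
#'   the group size.
#' @export
occlusion_report <- function(ensemble, vocab, docs,
                             group = "stroke_predictions",
                             candidate_words = vocabulary_unigrams(vocab)) {
  D <- length(docs)
  per_doc <- vector("list", D)
  base_X <- vectorize_corpus(docs, vocab)
  base_z <- ensemble_member_logits(ensemble, base_X)  # D x N
  if (D == 1) base_z <- matrix(base_z, nrow = 1)
  for (d in seq_len(D)) {
    tokens <- docs[[d]]
    present <- intersect(unique(tokens), candidate_words)
    if (length(present) == 0) {
      per_doc[[d]] <- setNames(numeric(0), character(0))
      next
    }
    Xv <- do.call(rbind, lapply(present, function(w) {
      vectorize(occlude_word(tokens, w), vocab)
    }))
    zv <- ensemble_member_logits(ensemble, Xv)  # variants x N
    if (length(present) == 1) zv <- matrix(zv, nrow = 1)
    imp <- rowMeans(matrix(base_z[d, ], nrow(zv), ncol(zv), byrow = TRUE) - zv)
    per_doc[[d]] <- setNames(imp, present)
  }
  all_words <- sort(unique(unlist(lapply(per_doc, names), use.names = FALSE)))
  rank_score <- numeric(length(all_words))
  occurrences <- integer(length(all_words))
  mean_impact <- numeric(length(all_words))
  imp_word <- unlist(lapply(per_doc, names), use.names = FALSE)
  imp_val <- unlist(per_doc, use.names = FALSE)
  f <- factor(imp_word, levels = all_words)
  rank_score <- as.numeric(tapply(imp_val, f, ranking_score, default = 0))
  occurrences <- as.integer(tapply(imp_val, f, length, default = 0L))
  mean_impact <- as.numeric(tapply(imp_val, f, mean, default = NA_real_))
  structure(
    list(per_word = data.frame(word = all_words, rank_score = rank_score,
                               occurrences = occurrences,
                               mean_impact = mean_impact, group = group,
                               stringsAsFactors = FALSE),
         per_doc_impacts = per_doc, D = D, group = group),
    class = "occlusion_report"
  )
}

#' @export
print.occlusion_report <- function(x, ...) {
  cat(sprintf("<occlusion_report> group %s: D = %d documents, %d words\n",
              x$group, x$D, nrow(x$per_word)))
  invisible(x)
}

#' Top-ranked words of an occlusion report
#'
#' Returns the `k` words with the largest positive (or most negative)
#' ranking scores, with their occurrence counts, in the layout of the
#' published attribution tables. Words occurring in no analysed document
#' are excluded; ties are broken lexicographically for a stable order.
#'
#' @param report an [occlusion_report()].
#' @param k list length (default 30; truncated when fewer words exist).
#' @param direction `"positive"` (stroke predictions) or `"negative"`
#'   (non-stroke predictions).
#' @return data.frame `rank`, `word`, `rank_score`, `occurrences`,
#'   `mean_impact`.
#' @export
top_words <- function(report, k = 30L, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  pw <- report$per_word[report$per_word$occurrences > 0, , drop = FALSE]
  o <- if (direction == "positive") order(-pw$rank_score, pw$word)
       else order(pw$rank_score, pw$word)
  pw <- pw[o, , drop = FALSE]
  pw <- head(pw, k)
  data.frame(rank = seq_len(nrow(pw)), word = pw$word,
             rank_score = pw$rank_score, occurrences = pw$occurrences,
             mean_impact = pw$mean_impact, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Select the median-F1 run for explainability
#'
#' The occlusion analysis is performed on the single training run whose
#' validation F1-score is the order-statistic median of the runs (hence an
#' odd run count is required; 11 in the full pipeline). If several runs tie
#' at the median value the earliest run index is returned.
#'
#' @param models list of trained ensembles (one per run).
#' @param f1s numeric vector of the runs' F1-scores.
#' @return list with `model`, `index`, `f1`.
#' @export
select_median_model <- function(models, f1s) {
  stopifnot(length(models) == length(f1s))
  n <- length(f1s)
  if (n %% 2 == 0) {
    stop(paste("even run count: the order-statistic median is ambiguous;",
               "drop a run or pass an odd number of runs"))
  }
  med_val <- sort(f1s)[(n + 1) / 2]
  idx <- which(f1s == med_val)[1]
  list(model = models[[idx]], index = idx, f1 = f1s[idx])
}

#' Render a top-words table as Markdown
#'
#' @param positive,negative data.frames from [top_words()].
#' @param d_pos,d_neg group sizes.
#' @return character vector of Markdown lines.
#' @export
format_occlusion_markdown <- function(positive, negative, d_pos, d_neg) {
  k <- max(nrow(positive), nrow(negative))
  pad <- function(df) {
    if (nrow(df) < k) {
      df <- rbind(df, data.frame(rank = seq(nrow(df) + 1L, k), word = "",
                                 rank_score = NA, occurrences = NA,
                                 mean_impact = NA))
    }
    df
  }
  p <- pad(positive); ng <- pad(negative)
  c(sprintf("| | Stroke predictions (D = %d) | D_w | Non-stroke predictions (D = %d) | D_w |",
            d_pos, d_neg),
    "|--:|---|--:|---|--:|",
    sprintf("| %d. | %s | %s | %s | %s |", seq_len(k),
            p$word, ifelse(is.na(p$occurrences), "", p$occurrences),
            ng$word, ifelse(is.na(ng$occurrences), "", ng$occurrences)))
}
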