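test_that("impact scores follow the mean logit difference", {
  # vocabulary {a, b}; two linear members with controllable logits
  v <- build_vocabulary(list(c("a", "b")), word_n = c(1, 1), char_n = NULL,
                        min_doc_freq = 1)
  col_a <- v$table$column[v$table$feature == "a"]
  col_b <- v$table$column[v$table$feature == "b"]
  w1 <- numeric(2); w1[c(col_a, col_b)] <- c(0.5, 0.5)  # doc "a b": z = 1.0
  w2 <- numeric(2); w2[c(col_a, col_b)] <- c(1.0, 1.0)  # doc "a b": z = 2.0
  ens <- fake_ensemble(list(linear_member(w1), linear_member(w2)))
  # occluding "b" drops the logits to (0.5, 1.0): impact (0.5 + 1.0) / 2
  expect_equal(impact_score(ens, v, c("a", "b"), "b"), 0.75)
  # a word absent from the document has exactly zero impact
  expect_identical(impact_score(ens, v, c("a", "a"), "b"), 0)
  # occluding every token leaves the empty-document logit
  z_full <- mean(c(1, 2))
  z_empty <- 0  # linear members with zero bias
  imp_a <- impact_score(ens, v, c("a", "b"), "a")
  imp_b <- impact_score(ens, v, c("a", "b"), "b")
  expect_equal(imp_a + imp_b, z_full - z_empty, tolerance = 1e-12)
})

test_that("ranking scores are signed squares summed over documents", {
  expect_equal(ranking_score(c(0.5, -0.5)), 0)
  expect_equal(ranking_score(2), 4)
  expect_equal(ranking_score(c(-3, 1)), -8)
  expect_equal(ranking_score(numeric(0)), 0)
})

test_that("occlusion reports match a brute-force oracle", {
  docs <- random_docs(20, lexicon = sprintf("t%02d", 1:8),
                      len_range = c(2, 6), seed = 42)
  v <- build_vocabulary(docs, c(1, 2), c(3, 4), 1)
  ens <- fake_ensemble(lapply(1:3, function(k) {
    fake_mlp(nrow(v$table), hidden = c(5L), seed = k, scale = 0.3)
  }))
  rep_fast <- occlusion_report(ens, v, docs, group = "stroke_predictions")

  # brute force: loops, naive vectorizer, naive forward pass
  words <- vocabulary_unigrams(v)
  brute <- list()
  for (w in words) {
    impacts <- c()
    for (d in seq_along(docs)) {
      if (w %in% docs[[d]]) {
        z0 <- mean(vapply(ens$members, function(m) {
          naive_mlp_logit(m, naive_vectorize(docs[[d]], v))
        }, numeric(1)))
        z1 <- mean(vapply(ens$members, function(m) {
          naive_mlp_logit(m, naive_vectorize(docs[[d]][docs[[d]] != w], v))
        }, numeric(1)))
        impacts <- c(impacts, z0 - z1)
      }
    }
    if (length(impacts)) {
      brute[[w]] <- c(r = sum(sign(impacts) * impacts^2),
                      D_w = length(impacts), mean = mean(impacts))
    }
  }
  expect_setequal(rep_fast$per_word$word, names(brute))
  for (w in names(brute)) {
    row <- rep_fast$per_word[rep_fast$per_word$word == w, ]
    expect_equal(row$rank_score, unname(brute[[w]]["r"]), tolerance = 1e-9)
    expect_equal(row$occurrences, unname(brute[[w]]["D_w"]))
    expect_equal(row$mean_impact, unname(brute[[w]]["mean"]),
                 tolerance = 1e-9)
  }

  # ranking scores are invariant to document order
  rep_perm <- occlusion_report(ens, v, rev(docs), group = "stroke_predictions")
  expect_equal(rep_perm$per_word, rep_fast$per_word)
})

test_that("negating the model swaps positive and negative word lists", {
  docs <- random_docs(15, lexicon = sprintf("t%02d", 1:6),
                      len_range = c(2, 5), seed = 14)
  v <- build_vocabulary(docs, c(1, 1), NULL, 1)
  m <- fake_mlp(nrow(v$table), hidden = c(4L), seed = 5)
  m_neg <- m
  m_neg$W[[2]] <- -m_neg$W[[2]]
  m_neg$b[[2]] <- -m_neg$b[[2]]
  r_pos <- occlusion_report(fake_ensemble(list(m)), v, docs)
  r_neg <- occlusion_report(fake_ensemble(list(m_neg)), v, docs)
  expect_equal(r_neg$per_word$rank_score, -r_pos$per_word$rank_score,
               tolerance = 1e-9)
  k <- 5
  expect_equal(top_words(r_neg, k, "negative")$word,
               top_words(r_pos, k, "positive")$word)
})

test_that("top_words truncates, excludes absent words, and orders stably", {
  rep0 <- structure(list(
    per_word = data.frame(
      word = c("a", "b", "c", "d"),
      rank_score = c(2, -1, 0, 0),
      occurrences = c(3L, 2L, 1L, 0L),
      mean_impact = c(0.5, -0.2, 0, NA),
      group = "stroke_predictions", stringsAsFactors = FALSE),
    per_doc_impacts = list(), D = 5, group = "stroke_predictions"),
    class = "occlusion_report")
  tw <- top_words(rep0, k = 10, "positive")
  expect_equal(tw$word, c("a", "c", "b"))  # d excluded: occurs nowhere
  expect_equal(nrow(top_words(rep0, k = 2, "positive")), 2)
  tw_neg <- top_words(rep0, k = 10, "negative")
  expect_equal(tw_neg$word[1], "b")
})

test_that("impacts are computed in logit space, not score space", {
  # a document scored ~1: sigmoid differences vanish, logit impacts do not
  v <- build_vocabulary(list(c("stroke", "filler")), word_n = c(1, 1),
                        char_n = NULL, min_doc_freq = 1)
  w <- numeric(2)
  w[v$table$column[v$table$feature == "stroke"]] <- 10
  w[v$table$column[v$table$feature == "filler"]] <- 5
  ens <- fake_ensemble(list(linear_member(w, b = 2)))
  doc <- c("stroke", "filler")
  sc0 <- sigmoid(mlp_logits(ens$members[[1]],
                            matrix(vectorize(doc, v), 1)))
  sc1 <- sigmoid(mlp_logits(ens$members[[1]],
                            matrix(vectorize(occlude_word(doc, "stroke"), v),
                                   1)))
  expect_lt(sc0 - sc1, 1e-3)              # score-space difference collapses
  expect_equal(impact_score(ens, v, doc, "stroke"), 10)  # logit impact
})

test_that("median-run selection follows the order statistic with ties to the first", {
  models <- as.list(letters[1:3])
  expect_equal(select_median_model(models, c(0.3, 0.5, 0.4))$index, 3)
  expect_equal(select_median_model(models, c(0.4, 0.4, 0.4))$index, 1)
  set.seed(3)
  f1s <- runif(11)
  sel <- select_median_model(as.list(1:11), f1s)
  expect_equal(sel$f1, sort(f1s)[6])
  expect_error(select_median_model(as.list(1:4), runif(4)), "even run count")
})
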