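#' Tokenize a raw transcript string
#'
#' Lowercases, splits on whitespace, and strips leading/trailing
#' punctuation from each token. Transcripts supplied as token vectors are
#' passed through untouched, so the pipeline accepts either form. The rule
#' deliberately keeps a "word" well defined: occlusion removes whole tokens.
#'
#' @param x a character scalar (raw text) or character vector (tokens).
#' @return character vector of tokens.
#' @export
tokenize <- function(x) {
  if (length(x) == 1 && grepl("\\s", x)) {
    x <- strsplit(tolower(x), "\\s+")[[1]]
  } else {
    x <- tolower(as.character(x))
  }
  x <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", x)
  x[nzchar(x)]
}

# character n-grams of one word, computed within word boundaries with an
# explicit boundary marker so grams never cross words
char_ngrams_of_word <- function(word, n_lo, n_hi, boundary = "_") {
  padded <- paste0(boundary, word, boundary)
  L <- nchar(padded)
  out <- character(0)
  for (n in n_lo:n_hi) {
    if (L >= n) {
      starts <- seq_len(L - n + 1L)
      out <- c(out, substring(padded, starts, starts + n - 1L))
    }
  }
  out
}

# all features of one token sequence, as strings tagged by type
doc_features <- function(tokens, word_n, char_n) {
  feats <- character(0)
  types <- character(0)
  n_tok <- length(tokens)
  if (!is.null(word_n)) {
    for (n in word_n[1]:word_n[2]) {
      if (n_tok >= n) {
        if (n == 1L) {
          g <- tokens
        } else {
          g <- tokens[seq_len(n_tok - n + 1L)]
          for (k in seq_len(n - 1L)) {
            g <- paste(g, tokens[(1L + k):(n_tok - n + 1L + k)])
          }
        }
        feats <- c(feats, g)
        types <- c(types, rep.int(sprintf("word%d", n), length(g)))
      }
    }
  }
  if (!is.null(char_n) && n_tok > 0) {
    cg <- unlist(lapply(tokens, char_ngrams_of_word, char_n[1], char_n[2]),
                 use.names = FALSE)
    feats <- c(feats, cg)
    types <- c(types, rep.int("char", length(cg)))
  }
  list(feature = feats, type = types)
}

# corpus-level feature stream: one pass over all documents, vectorised over
# the token stream rather than per document. Character n-grams are computed
# once per distinct token and expanded by occurrence. Returns parallel
# vectors `doc` (document index) and `key` ("type\rfeature").
corpus_features <- function(docs, word_n, char_n) {
  lens <- lengths(docs)
  tok <- unlist(docs, use.names = FALSE)
  doc <- rep.int(seq_along(docs), lens)
  out_doc <- integer(0)
  out_key <- character(0)
  if (!is.null(word_n)) {
    for (n in word_n[1]:word_n[2]) {
      if (n == 1L) {
        out_doc <- c(out_doc, doc)
        out_key <- c(out_key, paste0("word1\r", tok))
      } else if (length(tok) >= n) {
        g <- tok[seq_len(length(tok) - n + 1L)]
        same <- doc[seq_len(length(tok) - n + 1L)] ==
          doc[n:length(tok)]
        for (k in seq_len(n - 1L)) {
          g <- paste(g, tok[(1L + k):(length(tok) - n + 1L + k)])
        }
        out_doc <- c(out_doc, doc[seq_len(length(g))][same])
        out_key <- c(out_key, paste0(sprintf("word%d\r", n), g[same]))
      }
    }
  }
  if (!is.null(char_n) && length(tok)) {
    types <- unique(tok)
    grams_per_type <- lapply(types, char_ngrams_of_word,
                             char_n[1], char_n[2])
    n_grams <- lengths(grams_per_type)
    ti <- match(tok, types)
    out_doc <- c(out_doc, rep.int(doc, n_grams[ti]))
    out_key <- c(out_key,
                 paste0("char\r",
                        unlist(grams_per_type[ti], use.names = FALSE)))
  }
  list(doc = out_doc, key = out_key)
}

#' Build a fixed bag-of-words vocabulary
#'
#' Scans a training corpus for word n-grams and within-word character
#' n-grams, drops features seen in fewer than `min_doc_freq` documents, and
#' if more than `max_features` remain keeps those with the highest document
#' frequency (ties broken lexicographically). The procedure is
#' deterministic: the same corpus and settings always yield the same
#' vocabulary. Character n-grams are computed inside boundary-padded words
#' (`_word_`), so they never span a word boundary and every n-gram can be
#' traced to the word it came from — a property the occlusion analysis
#' relies on.
#'
#' @param docs list of token vectors (training folds only).
#' @param word_n integer length-2 range of word n-gram orders, or `NULL` to
#'   disable; default `c(1, 2)`.
#' @param char_n integer length-2 range of character n-gram orders, or
#'   `NULL` to disable; default `c(3, 5)`.
#' @param min_doc_freq drop features occurring in fewer documents.
#' @param max_features cap on vocabulary size.
#' @return object of class `strokecall_vocabulary`: data.frame `table`
#'   (feature, type, column, doc_freq), the n-gram settings, and a fast
#'   feature->column `index`.
#' @export
build_vocabulary <- function(docs, word_n = c(1L, 2L), char_n = c(3L, 5L),
                             min_doc_freq = 5L, max_features = 50000L) {
  if (length(docs) == 0) stop("empty corpus: no documents to scan")
  cf <- corpus_features(docs, word_n, char_n)
  if (length(cf$key) == 0) stop("empty corpus: no features found")
  uk <- unique(cf$key)
  j <- match(cf$key, uk)
  ## document frequency: count each (doc, feature) pair once
  pair_id <- (cf$doc - 1) * length(uk) + j
  keep <- !duplicated(pair_id)
  freq_all <- tabulate(j[keep], nbins = length(uk))
  sel <- freq_all >= min_doc_freq
  if (!any(sel)) {
    stop("no feature reaches min_doc_freq; lower the threshold")
  }
  nm <- uk[sel]
  freq <- freq_all[sel]
  ord <- order(-freq, nm)
  nm <- nm[ord]
  freq <- freq[ord]
  if (length(nm) > max_features) {
    nm <- nm[seq_len(max_features)]
    freq <- freq[seq_len(max_features)]
  }
  parts <- regmatches(nm, regexpr("\r", nm), invert = TRUE)
  tab <- data.frame(
    feature = vapply(parts, `[`, character(1), 2L),
    type = vapply(parts, `[`, character(1), 1L),
    column = seq_along(nm),
    doc_freq = freq,
    stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, word_n = word_n, char_n = char_n,
         min_doc_freq = min_doc_freq, max_features = max_features,
         index = setNames(tab$column, nm)),
    class = "strokecall_vocabulary"
  )
}

#' @export
print.strokecall_vocabulary <- function(x, ...) {
  cat(sprintf("<strokecall_vocabulary> %d features (%s)\n",
              nrow(x$table),
              paste(sprintf("%s: %d", names(table(x$table$type)),
                            table(x$table$type)), collapse = ", ")))
  invisible(x)
}

#' Word-unigram entries of a vocabulary
#'
#' @param vocab a `strokecall_vocabulary`.
#' @return character vector of the unigram features, in column order.
#' @export
vocabulary_unigrams <- function(vocab) {
  vocab$table$feature[vocab$table$type == "word1"]
}

#' Encode one transcript as a bag-of-words count vector
#'
#' Counts every vocabulary feature (word n-grams and within-word character
#' n-grams) in the token sequence; out-of-vocabulary material contributes
#' nothing.
#'
#' @param tokens character vector of tokens.
#' @param vocab a [build_vocabulary()] result.
#' @return numeric vector of length `nrow(vocab$table)`.
#' @export
vectorize <- function(tokens, vocab) {
  v <- numeric(nrow(vocab$table))
  f <- doc_features(tokens, vocab$word_n, vocab$char_n)
  if (length(f$feature)) {
    j <- unname(vocab$index[paste0(f$type, "\r", f$feature)])
    j <- j[!is.na(j)]
    if (length(j)) {
      cnt <- tabulate(j, nbins = length(v))
      v <- as.numeric(cnt)
    }
  }
  v
}

#' Encode a corpus as a sparse document-by-feature matrix
#'
#' @param docs list of token vectors.
#' @param vocab a [build_vocabulary()] result.
#' @param binary logical; if `TRUE` record presence instead of counts.
#' @return a `dgCMatrix` of dimension `length(docs)` x vocabulary size, with
#'   document names as rownames.
#' @export
vectorize_corpus <- function(docs, vocab, binary = FALSE) {
  cf <- corpus_features(docs, vocab$word_n, vocab$char_n)
  j_all <- unname(vocab$index[match(cf$key, names(vocab$index))])
  hit <- !is.na(j_all)
  i <- cf$doc[hit]
  j <- j_all[hit]
  V <- nrow(vocab$table)
  if (length(j) == 0) {
    X <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(docs), V))
  } else {
    X <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(docs), V))
  }
  if (binary) X@x[] <- 1
  rownames(X) <- names(docs)
  X
}

#' Remove every instance of a word from a token sequence
#'
#' The occlusion primitive: all copies of `word` are dropped and all other
#' tokens keep their order, so re-vectorizing the result discards every word
#' and character n-gram associated with the occluded word.
#'
#' @param tokens character vector.
#' @param word token to remove.
#' @return character vector without `word`.
#' @export
occlude_word <- function(tokens, word) {
  tokens[tokens != word]
}

#' Serialize / load a vocabulary as JSON
#'
#' @param vocab a `strokecall_vocabulary`.
#' @param path file path.
#' @return `write_vocabulary()` returns `path` invisibly;
#'   `read_vocabulary()` the vocabulary.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(
    list(table = vocab$table, word_n = vocab$word_n, char_n = vocab$char_n,
         min_doc_freq = vocab$min_doc_freq,
         max_features = vocab$max_features),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  obj <- jsonlite::fromJSON(path)
  tab <- as.data.frame(obj$table, stringsAsFactors = FALSE)
  structure(
    list(table = tab,
         word_n = if (is.null(obj$word_n)) NULL else as.integer(obj$word_n),
         char_n = if (is.null(obj$char_n)) NULL else as.integer(obj$char_n),
         min_doc_freq = obj$min_doc_freq, max_features = obj$max_features,
         index = setNames(tab$column, paste0(tab$type, "\r", tab$feature))),
    class = "strokecall_vocabulary"
  )
}
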