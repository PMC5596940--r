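#' Bundled English stop-word list
#'
#' A standard English stop-word list, stored one word per line and already
#' in post-tokenization form (contraction fragments like "don", "ll"
#' appear as separate entries because the tokenizer splits on
#' apostrophes).  Fully overridable: every consumer takes a `stopwords`
#' argument.
#'
#' @return character vector of stop words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "biodtm")
  readLines(path, warn = FALSE)
}

#' Token-pipeline configuration
#'
#' @param min_total_freq words whose summed count over the whole corpus is
#'   below this are pruned (default 2: "total frequency more than once").
#' @param tfidf_quantile quantile of the tf-idf score distribution used as
#'   the pruning threshold (default 0.25, the first quartile); must be in
#'   `[0, 1)`, or `NA` to disable the tf-idf filter entirely.  Words are
#'   kept when their score is strictly greater than the threshold, so the
#'   cut sits "a bit more than" the quantile; `tfidf_margin` adds an
#'   explicit additive margin on top.
#' @param tfidf_margin additive margin on the tf-idf threshold (default 0).
#' @param min_token_chars tokens shorter than this are discarded
#'   (default 2).
#' @param drop_numeric drop purely numeric tokens (default TRUE).
#' @param stopwords stop-word list (default [default_stopwords()]).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_total_freq = 2L,
                            tfidf_quantile = 0.25,
                            tfidf_margin = 0,
                            min_token_chars = 2L,
                            drop_numeric = TRUE,
                            stopwords = default_stopwords()) {
  stopifnot(
    min_total_freq >= 1L,
    is.na(tfidf_quantile) || (tfidf_quantile >= 0 && tfidf_quantile < 1),
    tfidf_margin >= 0,
    min_token_chars >= 1L
  )
  structure(
    list(min_total_freq = as.integer(min_total_freq),
         tfidf_quantile = tfidf_quantile,
         tfidf_margin = tfidf_margin,
         min_token_chars = as.integer(min_token_chars),
         drop_numeric = drop_numeric,
         stopwords = stopwords),
    class = "pipeline_config"
  )
}

#' Tokenize free text
#'
#' Lowercases and splits on every non-alphanumeric character (hyphens and
#' apostrophes are split points), then removes purely numeric tokens,
#' tokens shorter than `min_chars`, and stop words.  No stemming is done
#' here; see [porter_stem()].
#'
#' @param text character vector of free text (typically title + abstract).
#' @param stopwords character vector of stop words.
#' @param min_chars minimum token length kept.
#' @param drop_numeric drop purely numeric tokens.
#' @return list of character vectors, one per element of `text`.
#' @examples
#' tokenize_text("Ginseng's anti-cancer effects.", stopwords = character())
#' @export
tokenize_text <- function(text, stopwords = default_stopwords(),
                          min_chars = 2L, drop_numeric = TRUE) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")
  lapply(toks, function(tk) {
    tk <- tk[nchar(tk) >= min_chars]
    if (drop_numeric) tk <- tk[!grepl("^[0-9]+$", tk)]
    tk[!(tk %in% stopwords)]
  })
}

#' Build the dictionary-restricted corpus matrix
#'
#' Runs the full document-side pipeline: tokenization of title + abstract,
#' Porter stemming, restriction to stems present in the dictionary
#' ("qualified in the bio-dictionary"), per-document count aggregation,
#' then the two vocabulary filters in order — total-frequency first, tf-idf
#' second.  Following the single-pass convention, the tf-idf scores (and
#' their quantile threshold) are computed once on the dictionary-restricted
#' matrix before either filter removes anything.
#'
#' Documents left empty at any stage are dropped and reported; a slice left
#' with zero documents is an error naming the slice.
#'
#' @param docs document data.frame with `slice_index` set (see
#'   [assign_slices()]).
#' @param dict a `bio_dictionary`.
#' @param cfg a [pipeline_config()].
#' @param n_slices number of slices `T` (defaults to the maximum
#'   `slice_index` present).
#' @return a [corpus_matrix()] with attribute `drop_report`: a list with
#'   counts of documents dropped when emptied by dictionary restriction and
#'   by the vocabulary filters.
#' @export
build_matrix <- function(docs, dict, cfg = pipeline_config(),
                         n_slices = max(docs$slice_index)) {
  stopifnot(inherits(dict, "bio_dictionary"),
            inherits(cfg, "pipeline_config"),
            !anyNA(docs$slice_index))
  token_lists <- tokenize_text(
    paste(docs$title, docs$abstract),
    stopwords = cfg$stopwords,
    min_chars = cfg$min_token_chars,
    drop_numeric = cfg$drop_numeric
  )
  kept_stems <- lapply(token_lists, function(tk) {
    st <- porter_stem(tk)
    st[dict_contains(dict, st)]
  })
  nonempty <- vapply(kept_stems, length, integer(1)) > 0L
  dropped_dict <- sum(!nonempty)

  vocab <- sort(unique(unlist(kept_stems, use.names = FALSE)),
                method = "radix")
  if (!length(vocab)) {
    stop("no document token survives the dictionary restriction")
  }
  slice_of <- docs$slice_index[nonempty]
  ids <- docs$record_id[nonempty]
  stems_kept <- kept_stems[nonempty]
  slices <- lapply(seq_len(n_slices), function(t) {
    sel <- which(slice_of == t)
    lapply(sel, function(i) {
      tab <- table(match(stems_kept[[i]], vocab))  # names sort numerically
      list(idx = as.integer(names(tab)) - 1L, cnt = as.integer(tab))
    })
  })
  doc_ids <- lapply(seq_len(n_slices), function(t) ids[slice_of == t])
  m <- corpus_matrix(vocab, slices, doc_ids)

  # vocabulary filters; tf-idf threshold computed on the pre-filter matrix
  m1 <- filter_total_frequency(m, cfg$min_total_freq)
  m2 <- if (is.na(cfg$tfidf_quantile)) {
    m1
  } else {
    filter_tfidf(m1, cfg$tfidf_quantile, margin = cfg$tfidf_margin,
                 reference = m)
  }
  dropped_filters <- corpus_n_docs(m) - corpus_n_docs(m2)

  empty_slices <- which(vapply(m2$slices, length, integer(1)) == 0L)
  if (length(empty_slices)) {
    stop("slice(s) left with zero documents after filtering: ",
         paste(empty_slices, collapse = ", "))
  }
  attr(m2, "drop_report") <- list(
    dropped_empty_after_dictionary = dropped_dict,
    dropped_empty_after_filters = dropped_filters
  )
  m2
}

# Restrict a corpus_matrix to the words whose 1-based positions are in
# `keep` (logical V-vector); reindexes the vocabulary densely and drops
# documents left empty.
restrict_vocabulary <- function(m, keep) {
  new_pos <- cumsum(keep)           # old 1-based -> new 1-based
  vocab <- m$vocab[keep]
  dropped <- 0L
  slices <- vector("list", length(m$slices))
  doc_ids <- if (is.null(m$doc_ids)) NULL else vector("list", length(m$slices))
  for (t in seq_along(m$slices)) {
    out <- list()
    keep_doc <- logical(length(m$slices[[t]]))
    for (j in seq_along(m$slices[[t]])) {
      d <- m$slices[[t]][[j]]
      sel <- keep[d$idx + 1L]
      if (any(sel)) {
        out[[length(out) + 1L]] <- list(
          idx = as.integer(new_pos[d$idx[sel] + 1L] - 1L),
          cnt = d$cnt[sel]
        )
        keep_doc[j] <- TRUE
      } else {
        dropped <- dropped + 1L
      }
    }
    slices[[t]] <- out
    if (!is.null(doc_ids)) doc_ids[[t]] <- m$doc_ids[[t]][keep_doc]
  }
  res <- structure(
    list(vocab = vocab, slices = slices, doc_ids = doc_ids),
    class = "corpus_matrix"
  )
  attr(res, "dropped_docs") <- dropped
  res
}

#' Prune rare words by total corpus frequency
#'
#' Removes every word whose summed count over all slices is below
#' `min_total`; the vocabulary is reindexed densely and documents left
#' empty are dropped (count in attribute `dropped_docs`).
#'
#' @param m a [corpus_matrix()].
#' @param min_total minimum total count a word needs to survive.
#' @return the filtered `corpus_matrix`.
#' @export
filter_total_frequency <- function(m, min_total = 2L) {
  stopifnot(min_total >= 1L)
  if (min_total == 1L) return(m)
  restrict_vocabulary(m, corpus_word_totals(m) >= min_total)
}

#' Prune words by tf-idf score quantile
#'
#' Scores every word as `tf * ln(D / df)` with `tf` its total corpus
#' count, `df` the number of documents containing it and `D` the total
#' document count, all computed on `reference` (by default the input
#' itself; the pipeline passes the dictionary-restricted pre-filter
#' matrix).  The threshold is the `quantile`-quantile (linear
#' interpolation) of all reference scores plus `margin`; words are kept
#' when their score is strictly greater than the threshold.
#'
#' A word present in every document has `idf = ln(1) = 0`, score 0, and is
#' removed whenever the threshold is non-negative.
#'
#' @param m a [corpus_matrix()] whose vocabulary is a subset of
#'   `reference`'s.
#' @param quantile quantile of the score distribution, in `[0, 1)`.
#' @param margin additive margin on the threshold (default 0).
#' @param reference matrix on which scores, `D` and the threshold are
#'   computed.
#' @return the filtered `corpus_matrix`.
#' @export
filter_tfidf <- function(m, quantile = 0.25, margin = 0, reference = m) {
  stopifnot(quantile >= 0, quantile < 1)
  scores <- tfidf_scores(reference)
  threshold <- stats::quantile(scores, probs = quantile, names = FALSE,
                               type = 7) + margin
  score_of <- scores[match(m$vocab, reference$vocab)]
  if (anyNA(score_of)) {
    stop("matrix vocabulary is not a subset of the reference vocabulary")
  }
  restrict_vocabulary(m, score_of > threshold)
}

#' Corpus-pruning tf-idf scores
#'
#' Vocabulary entries that occur in no document (possible in hand-built
#' matrices; never produced by [build_matrix()]) get score 0, the
#' `tf -> 0` limit, so any positive threshold prunes them.
#'
#' @param m a [corpus_matrix()].
#' @return named numeric vector, `tf(w) * ln(D / df(w))` per word.
#' @export
tfidf_scores <- function(m) {
  tf <- corpus_word_totals(m)
  df <- corpus_doc_freq(m)
  D <- corpus_n_docs(m)
  s <- ifelse(tf > 0, tf * log(D / pmax(df, 1L)), 0)
  stats::setNames(s, m$vocab)
}
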