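# Shared fixtures and independent oracles.  Oracles deliberately avoid the
# package's own code paths: filters are re-derived by direct enumeration
# over a dense matrix representation.

# Random sparse corpus with guaranteed non-empty docs and slices.
random_corpus <- function(V = 10L, T_ = 3L, docs_per_slice = 4L,
                          max_words = 6L, max_count = 4L) {
  vocab <- sprintf("w%03d", seq_len(V))
  slices <- lapply(seq_len(T_), function(t) {
    lapply(seq_len(docs_per_slice), function(j) {
      n <- sample.int(min(max_words, V), 1L)
      idx <- sort(sample.int(V, n)) - 1L
      list(idx = idx, cnt = sample.int(max_count, n, replace = TRUE))
    })
  })
  corpus_matrix(vocab, slices)
}

# Dense docs x V count matrix plus doc->slice map; the oracle's
# representation of a corpus_matrix.
dense_counts <- function(m) {
  V <- length(m$vocab)
  rows <- list()
  slice_of <- integer(0)
  for (t in seq_along(m$slices)) {
    for (d in m$slices[[t]]) {
      x <- numeric(V)
      x[d$idx + 1L] <- d$cnt
      rows[[length(rows) + 1L]] <- x
      slice_of <- c(slice_of, t)
    }
  }
  list(counts = do.call(rbind, rows), slice = slice_of, vocab = m$vocab)
}

# Brute-force oracle for the two vocabulary filters: word survival is
# recomputed from the dense matrix by literal application of the rules.
# Returns the surviving word set (character).
oracle_filter_words <- function(m, min_total, quantile, margin = 0) {
  dd <- dense_counts(m)
  tf <- colSums(dd$counts)
  keep1 <- tf >= min_total
  df <- colSums(dd$counts > 0)
  D <- nrow(dd$counts)
  score <- ifelse(tf > 0, tf * log(D / pmax(df, 1)), 0)  # unused words: 0
  thr <- as.numeric(stats::quantile(score, quantile, type = 7)) + margin
  keep2 <- score > thr
  dd$vocab[keep1 & keep2]
}

# Empirical word distribution of one slice (1-based V vector).
slice_empirical <- function(m, t) {
  x <- numeric(length(m$vocab))
  for (d in m$slices[[t]]) x[d$idx + 1L] <- x[d$idx + 1L] + d$cnt
  x / sum(x)
}

pooled_empirical <- function(m) {
  x <- numeric(length(m$vocab))
  for (sl in m$slices) for (d in sl) x[d$idx + 1L] <- x[d$idx + 1L] + d$cnt
  x / sum(x)
}

slice_token_total <- function(m, t) {
  sum(vapply(m$slices[[t]], function(d) sum(d$cnt), numeric(1)))
}

# Mean TV distance between two models under the best topic permutation.
matched_mean_tv <- function(phi_true, phi_fit) {
  K <- length(phi_true)
  T_ <- ncol(phi_true[[1L]])
  cost <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      cost[i, j] <- mean(vapply(
        seq_len(T_),
        function(t) tv_distance(phi_true[[i]][, t], phi_fit[[j]][, t]),
        numeric(1)
      ))
    }
  }
  match_topics(cost)
}

# A small well-formed MEDLINE export used across corpus_io tests.
medline_fixture_lines <- function() {
  c(
    "PMID- 101",
    "TI  - Ginseng and",
    "      memory improvement.",
    "AB  - Panax ginseng improves memory",
    "      in aged rats.",
    "DP  - 1999 Jan-Feb",
    "",
    "PMID- 102",
    "TI  - No abstract here.",
    "DP  - 2001",
    "",
    "PMID- 103",
    "TI  - Heart failure study.",
    "AB  - Ginsenosides reduce heart failure.",
    "AB  - Second abstract chunk.",
    "DP  - 2010 Dec",
    ""
  )
}
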