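#' Specification of a synthetic time-sliced corpus
#'
#' Describes a corpus drawn from exactly the generative process the model
#' fits: `K` topic chains random-walking over `T` slices, documents with
#' Dirichlet topic mixtures, tokens sampled topic-then-word.  The defaults
#' emulate the shape of the 1975-2017 ginseng abstract collection: 20
#' topics over 16 slices with about 400 articles per slice; vocabulary
#' size and document length default to values typical of
#' dictionary-restricted abstracts (2000 distinct stems, 120 content
#' tokens per title + abstract).
#'
#' @param K number of topics.
#' @param V vocabulary size (pseudo-words `w0001`, ..., chosen so Porter
#'   stemming is the identity on them).
#' @param T_ number of time slices.
#' @param docs_per_slice documents per slice.
#' @param mean_doc_length Poisson mean of document length (truncated to be
#'   at least 1 token).
#' @param drift_sd per-coordinate standard deviation of the Gaussian
#'   random walk on the natural parameters between adjacent slices.
#' @param topic_sd standard deviation of the Gaussian perturbation that
#'   separates the initial topics from the common base distribution
#'   (default 1: top words roughly an order of magnitude above base rate,
#'   as in fitted text models).
#' @param alpha symmetric Dirichlet concentration of document mixtures.
#' @param seed integer seed; everything downstream is reproducible from it.
#' @param slice_years optional `T x 2` matrix (or data.frame) of inclusive
#'   year ranges per slice, required only for pseudo-MEDLINE emission.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(K = 20L, V = 2000L, T_ = 16L,
                           docs_per_slice = 400L, mean_doc_length = 120,
                           drift_sd = 0.1, topic_sd = 1, alpha = 0.1,
                           seed = 1L, slice_years = NULL) {
  stopifnot(K >= 1L, V >= 2L, T_ >= 1L, docs_per_slice >= 1L,
            mean_doc_length > 0, drift_sd >= 0, topic_sd >= 0, alpha > 0)
  if (!is.null(slice_years)) {
    slice_years <- as.matrix(slice_years)
    stopifnot(nrow(slice_years) == T_, ncol(slice_years) == 2L)
  }
  structure(
    list(K = as.integer(K), V = as.integer(V), T_ = as.integer(T_),
         docs_per_slice = as.integer(docs_per_slice),
         mean_doc_length = mean_doc_length, drift_sd = drift_sd,
         topic_sd = topic_sd, alpha = alpha, seed = as.integer(seed),
         slice_years = slice_years),
    class = "synthetic_spec"
  )
}

# Stem-invariant pseudo-words: letter prefix + zero-padded digits, so
# lexicographic order equals index order and Porter stemming is a no-op.
pseudo_words <- function(V, prefix = "w") {
  sprintf("%s%0*d", prefix, max(4L, nchar(as.character(V))), seq_len(V))
}

#' Sample ground-truth topic chains
#'
#' Draws `b[k, 1]` as a mean-centered Zipf-like log-frequency base plus
#' topic-specific Gaussian noise (sd `topic_sd`), then random-walks
#' `b[k, t] = b[k, t - 1] + N(0, drift_sd^2 I)` with mean-centering after
#' every step; `phi` is the per-slice softmax.  Deterministic given
#' `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `b` and `phi`, each a list of `K` `V x T` matrices,
#'   and `vocab` (the pseudo-words).
#' @export
sample_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  V <- spec$V
  base <- log(1 / seq_len(V))       # Zipf-like word-frequency profile
  base <- base - mean(base)
  b <- lapply(seq_len(spec$K), function(k) {
    B <- matrix(NA_real_, V, spec$T_)
    col <- base + stats::rnorm(V, sd = spec$topic_sd)
    B[, 1L] <- col - mean(col)
    for (t in seq_len(spec$T_)[-1L]) {
      col <- B[, t - 1L] + stats::rnorm(V, sd = spec$drift_sd)
      B[, t] <- col - mean(col)
    }
    B
  })
  phi <- lapply(b, function(B) apply(B, 2L, softmax))
  phi <- lapply(phi, function(P) matrix(P, nrow = V))
  list(b = b, phi = phi, vocab = pseudo_words(V))
}

#' Sample a corpus from ground truth
#'
#' Per document: length `~ Poisson(mean_doc_length)` truncated to at least
#' 1; mixture `theta ~ Dirichlet(alpha)`; each token drawn
#' topic-then-word from the slice's `phi`.  Counts are aggregated into a
#' [corpus_matrix()].  Uses its own seeded RNG stream
#' (`spec$seed + 1`, so truth and corpus draws are independent).
#'
#' @param spec a [synthetic_spec()].
#' @param truth result of [sample_ground_truth()] for the same spec.
#' @return list with `matrix` (the `corpus_matrix`), `theta` (documents x
#'   K true mixtures), `topic_counts` (documents x K true token
#'   assignment counts) and `doc_slice`.
#' @export
sample_corpus <- function(spec, truth) {
  stopifnot(inherits(spec, "synthetic_spec"),
            length(truth$phi) == spec$K,
            nrow(truth$phi[[1L]]) == spec$V)
  set.seed(spec$seed + 1L)
  K <- spec$K
  V <- spec$V
  n_docs <- spec$T_ * spec$docs_per_slice
  theta <- matrix(NA_real_, n_docs, K)
  topic_counts <- matrix(0L, n_docs, K)
  doc_slice <- rep(seq_len(spec$T_), each = spec$docs_per_slice)
  slices <- vector("list", spec$T_)
  d_i <- 0L
  for (t in seq_len(spec$T_)) {
    docs <- vector("list", spec$docs_per_slice)
    for (j in seq_len(spec$docs_per_slice)) {
      d_i <- d_i + 1L
      len <- max(1L, stats::rpois(1L, spec$mean_doc_length))
      th <- stats::rgamma(K, shape = spec$alpha)
      th <- th / sum(th)
      theta[d_i, ] <- th
      z <- sample.int(K, len, replace = TRUE, prob = th)
      zc <- tabulate(z, nbins = K)
      topic_counts[d_i, ] <- zc
      wc <- integer(V)
      for (k in which(zc > 0L)) {
        w <- sample.int(V, zc[k], replace = TRUE, prob = truth$phi[[k]][, t])
        wc <- wc + tabulate(w, nbins = V)
      }
      pos <- which(wc > 0L)
      docs[[j]] <- list(idx = pos - 1L, cnt = wc[pos])
    }
    slices[[t]] <- docs
  }
  list(
    matrix = corpus_matrix(truth$vocab, slices),
    theta = theta, topic_counts = topic_counts, doc_slice = doc_slice
  )
}

#' Emit a synthetic corpus as pseudo-MEDLINE text
#'
#' Writes one MEDLINE-format record per document — sequential `PMID`, a
#' `TI` made of the document's first (up to) five tokens, an `AB` holding
#' the remaining tokens, and a `DP` year inside the document's slice range
#' — plus a matching term-list dictionary file containing every
#' vocabulary pseudo-word and 20% distractor pseudo-words (`z...`-prefixed)
#' that occur in no document.  Tokens are emitted in word-index order, so
#' re-ingesting the file through [parse_medline()], [build_dictionary()]
#' and [build_matrix()] with filters off reproduces `m` exactly.
#'
#' When a document has a single token it all goes to `AB` and the title
#' falls back to a fixed non-dictionary phrase, keeping the abstract
#' non-empty.
#'
#' @param spec a [synthetic_spec()] with `slice_years` set.
#' @param m the [corpus_matrix()] to emit (typically from
#'   [sample_corpus()]).
#' @param medline_path output path of the MEDLINE-format file.
#' @param dict_path output path of the term-list file.
#' @param distractor_frac fraction of additional never-used dictionary
#'   words (default 0.2).
#' @return invisibly, a list with both paths and the record count.
#' @export
emit_pseudo_medline <- function(spec, m, medline_path, dict_path,
                                distractor_frac = 0.2) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(spec$slice_years)) {
    stop("spec$slice_years is required for pseudo-MEDLINE emission")
  }
  blocks <- list()
  pmid <- 0L
  for (t in seq_along(m$slices)) {
    year <- spec$slice_years[t, 1L]
    for (doc in m$slices[[t]]) {
      pmid <- pmid + 1L
      tokens <- rep(m$vocab[doc$idx + 1L], doc$cnt)
      n_title <- min(5L, length(tokens) - 1L)
      title <- if (n_title >= 1L) {
        paste(tokens[seq_len(n_title)], collapse = " ")
      } else {
        "Untitled synthetic record"
      }
      abstract <- paste(tokens[(n_title + 1L):length(tokens)],
                        collapse = " ")
      blocks[[pmid]] <- c(
        paste0("PMID- ", pmid),
        paste0("TI  - ", title),
        paste0("AB  - ", abstract),
        paste0("DP  - ", year),
        ""
      )
    }
  }
  writeLines(unlist(blocks, use.names = FALSE), medline_path)
  n_distract <- ceiling(distractor_frac * length(m$vocab))
  distractors <- pseudo_words(n_distract, prefix = "z")
  writeLines(c(m$vocab, distractors), dict_path)
  invisible(list(medline = medline_path, dictionary = dict_path,
                 n_records = pmid))
}
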