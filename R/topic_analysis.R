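#' Top words of a topic at one slice
#'
#' The `n` vocabulary words with the largest probability under
#' `phi[k, t]`, in descending order; exact ties are broken by ascending
#' word index.  `n` larger than the vocabulary returns all words.
#'
#' @param model a `dtm_model`.
#' @param k topic index.
#' @param t slice index.
#' @param n number of words (default 10, the per-slice table size).
#' @return character vector of words.
#' @export
top_words <- function(model, k, t, n = 10L) {
  stopifnot(n >= 1L)
  p <- topic_distribution(model, k, t)
  ord <- order(-p, seq_along(p))
  model$vocab[ord[seq_len(min(n, length(p)))]]
}

#' Whole-period top words of a topic
#'
#' Words ranked by the unweighted mean of `phi[k, t]` over all slices —
#' the one-row-per-topic summary style of a whole-period topic table.
#' Same tie rule as [top_words()].
#'
#' @inheritParams top_words
#' @return character vector of words.
#' @export
overall_top_words <- function(model, k, n = 10L) {
  stopifnot(inherits(model, "dtm_model"), n >= 1L)
  if (k < 1L || k > model$K) stop("topic index out of range: ", k)
  p <- rowMeans(model$phi[[k]])
  ord <- order(-p, seq_along(p))
  model$vocab[ord[seq_len(min(n, length(p)))]]
}

#' Per-slice topic strength
#'
#' The token-weighted expected topic share: for topic `k` and slice `t`,
#' the expected number of slice-`t` tokens assigned to `k` under the
#' variational posterior, divided by the slice's total token count.
#' Columns sum to one by construction, so the matrix feeds straight into
#' the river layout with conserved mass.
#'
#' @param model a `dtm_model`.
#' @param posterior the `dtm_posterior` from the same fit.
#' @param m the [corpus_matrix()] that was fitted.
#' @return a `K x T` matrix of class `topic_strength`; errors on an empty
#'   slice.
#' @export
topic_strength <- function(model, posterior, m) {
  stopifnot(inherits(posterior, "dtm_posterior"),
            length(m$slices) == model$T)
  n_docs_slice <- vapply(m$slices, length, integer(1))
  if (any(n_docs_slice == 0L)) {
    stop("empty slice(s): ", paste(which(n_docs_slice == 0L), collapse = ", "))
  }
  s <- matrix(0, model$K, model$T)
  tok <- numeric(model$T)
  for (d in seq_along(posterior$resp)) {
    rd <- posterior$resp[[d]]
    t <- posterior$doc_slice[d]
    s[, t] <- s[, t] + colSums(rd$r * rd$cnt)
    tok[t] <- tok[t] + sum(rd$cnt)
  }
  s <- sweep(s, 2L, tok, "/")
  structure(s, class = c("topic_strength", "matrix"))
}

#' Export topic tables
#'
#' Writes two deterministic CSVs: a summary with one row per topic (topic
#' id and its comma-joined whole-period top-`n` words) and a long-format
#' per-slice table with columns `topic`, `slice`, `rank`, `word`,
#' `probability`.
#'
#' @param model a `dtm_model`.
#' @param n words per (topic, slice).
#' @param path path of the summary CSV.
#' @param long_path path of the long-format CSV (default: summary path
#'   with `_slices` appended before the extension).
#' @return invisibly, a list with both paths.
#' @export
export_topic_table <- function(model, n, path,
                               long_path = default_long_path(path)) {
  stopifnot(inherits(model, "dtm_model"), n >= 1L)
  summary_df <- data.frame(
    topic = seq_len(model$K),
    top_words = vapply(
      seq_len(model$K),
      function(k) paste(overall_top_words(model, k, n), collapse = ", "),
      character(1)
    )
  )
  utils::write.csv(summary_df, path, row.names = FALSE)
  rows <- vector("list", model$K * model$T)
  i <- 0L
  for (k in seq_len(model$K)) {
    for (t in seq_len(model$T)) {
      p <- topic_distribution(model, k, t)
      ord <- order(-p, seq_along(p))[seq_len(min(n, length(p)))]
      i <- i + 1L
      rows[[i]] <- data.frame(
        topic = k, slice = t, rank = seq_along(ord),
        word = model$vocab[ord], probability = p[ord]
      )
    }
  }
  long_df <- do.call(rbind, rows)
  utils::write.csv(long_df, long_path, row.names = FALSE)
  invisible(list(summary = path, long = long_path))
}

default_long_path <- function(path) {
  ext <- tools::file_ext(path)
  if (nzchar(ext)) {
    sub(paste0("\\.", ext, "$"), paste0("_slices.", ext), path)
  } else {
    paste0(path, "_slices")
  }
}

#' Write a topic-strength matrix as CSV
#'
#' Long-lived exchange format for the river stage: a `T x K` table, one
#' row per slice, with an optional slice-label column.
#'
#' @param s a `topic_strength` matrix (`K x T`).
#' @param path output CSV path.
#' @param slice_labels optional character vector of length `T` (e.g. year
#'   ranges).
#' @return `path`, invisibly.
#' @export
write_strengths <- function(s, path, slice_labels = NULL) {
  df <- as.data.frame(t(unclass(s)))
  names(df) <- paste0("topic", seq_len(nrow(s)))
  if (!is.null(slice_labels)) {
    df <- cbind(slice = slice_labels, df)
  } else {
    df <- cbind(slice = seq_len(ncol(s)), df)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_strengths
#' @export
read_strengths <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- df[[1L]]
  s <- t(as.matrix(df[, -1L, drop = FALSE]))
  dimnames(s) <- NULL
  attr(s, "slice_labels") <- as.character(labels)
  structure(s, class = c("topic_strength", "matrix"))
}
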