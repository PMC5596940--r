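#' Build a biomedical dictionary of stemmed unigrams
#'
#' Collapses any number of term lists (medical dictionaries, side-effect
#' resources, gene-symbol tables, ...) into a single whitelist of stems.
#' Because the topic model is a bag of single words, multi-word terms are
#' split apart: every term is lowercased and split on whitespace, hyphens
#' and all other punctuation; stop words, purely numeric tokens and
#' single-character tokens are discarded; each surviving unigram is Porter
#' stemmed; the union over all sources is deduplicated.
#'
#' @param term_lists named list; each element a character vector of raw
#'   terms from one source (names are the source names).
#' @param stopwords character vector of stop words (may be empty); applied
#'   to unigrams before stemming.
#' @return an object of class `bio_dictionary`: list with `stems` (sorted
#'   character vector) and `source_counts` (named integer vector of raw
#'   term counts per source).  Errors if the final stem set is empty.
#' @examples
#' build_dictionary(list(x = c("heart attack", "heart-failure")))
#' @export
build_dictionary <- function(term_lists, stopwords = character()) {
  stopifnot(is.list(term_lists), length(term_lists) >= 1L)
  if (is.null(names(term_lists)) || any(!nzchar(names(term_lists)))) {
    stop("term_lists must be a named list (one name per source)")
  }
  all_stems <- character()
  source_counts <- integer()
  for (src in names(term_lists)) {
    terms <- term_lists[[src]]
    source_counts[src] <- length(terms)
    toks <- unlist(strsplit(tolower(terms), "[^a-z0-9]+"), use.names = FALSE)
    toks <- toks[nzchar(toks)]
    toks <- toks[nchar(toks) >= 2L]
    toks <- toks[!grepl("^[0-9]+$", toks)]
    toks <- setdiff(toks, stopwords)
    all_stems <- c(all_stems, porter_stem(unique(toks)))
  }
  # stemming can itself land on a stop word ("caring" -> "care"); keep the
  # no-stopword invariant on the final set
  all_stems <- setdiff(all_stems, stopwords)
  stems <- sort(unique(all_stems), method = "radix")
  if (!length(stems)) {
    stop("dictionary is empty after tokenization and filtering")
  }
  structure(
    list(stems = stems, source_counts = source_counts),
    class = "bio_dictionary"
  )
}

#' Dictionary membership test
#'
#' @param dict a `bio_dictionary`.
#' @param stems character vector of stems (callers must stem first:
#'   `"hearts"` is not found even if `"heart"` is present).
#' @return logical vector, `TRUE` where the stem is in the dictionary.
#' @export
dict_contains <- function(dict, stems) {
  stopifnot(inherits(dict, "bio_dictionary"))
  stems %in% dict$stems
}

#' @export
print.bio_dictionary <- function(x, ...) {
  cat(sprintf(
    "bio_dictionary: %d stems from %d source(s) [%s]\n",
    length(x$stems), length(x$source_counts),
    paste(sprintf("%s: %d", names(x$source_counts), x$source_counts),
          collapse = ", ")
  ))
  invisible(x)
}

#' Write / read a dictionary
#'
#' The dictionary is stored as plain text, one stem per line, with a JSON
#' sidecar `<path>.json` recording the per-source raw term counts.
#'
#' @param dict a `bio_dictionary`.
#' @param path output path for the stem list.
#' @return `write_dictionary` returns `path` invisibly; `read_dictionary`
#'   the reconstructed `bio_dictionary` (with empty `source_counts` if the
#'   sidecar is absent).
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "bio_dictionary"))
  writeLines(dict$stems, path)
  jsonlite::write_json(
    list(source_counts = as.list(dict$source_counts)),
    paste0(path, ".json"),
    auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  stems <- readLines(path, warn = FALSE)
  stems <- stems[nzchar(stems)]
  sidecar <- paste0(path, ".json")
  source_counts <- if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar)$source_counts
    stats::setNames(vapply(sc, as.integer, integer(1)), names(sc))
  } else {
    integer()
  }
  structure(
    list(stems = sort(unique(stems), method = "radix"),
         source_counts = source_counts),
    class = "bio_dictionary"
  )
}
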