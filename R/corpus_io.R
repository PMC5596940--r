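#' Parse a MEDLINE-format export into documents
#'
#' Reads the tagged-record format produced by PubMed's
#' "Send to: File, Format: MEDLINE" export: each record is a block of
#' `TAG - value` lines (tag padded to four characters), continuation lines
#' are indented, records are separated by blank lines.  One document is
#' produced per record that carries a PMID, a title (`TI`), an abstract
#' (`AB`) and a publication date (`DP`) containing a 4-digit year; records
#' missing any of these — in practice almost always the abstract — are
#' skipped and counted.
#'
#' Continuation lines are folded into the preceding field with a single
#' space.  Repeated `AB` fields are concatenated in order (single space);
#' for any other repeated tag the first occurrence wins.  The year is the
#' first 4-digit token in `DP`, so month/season suffixes ("1999 Jan-Feb")
#' are tolerated.
#'
#' @param path path to a MEDLINE-format text file, or a character vector of
#'   lines (useful in tests).
#' @return list with `documents` — a data.frame with columns `record_id`,
#'   `title`, `abstract`, `year`, `slice_index` (all `NA` until
#'   [assign_slices()] is called) — and `skipped`, a named integer vector of
#'   skip counts by reason (`no_abstract`, `no_title`, `no_pmid`,
#'   `no_year`).
#' @export
parse_medline <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    path
  }
  tag_re <- "^([A-Z0-9]{1,4})\\s*- "
  records <- list()
  fields <- list()
  cur_tag <- NULL
  flush_record <- function() {
    if (length(fields)) records[[length(records) + 1L]] <<- fields
    fields <<- list()
    cur_tag <<- NULL
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) {
      flush_record()
    } else if (grepl(tag_re, line)) {
      m <- regexpr(tag_re, line)
      cur_tag <- sub(tag_re, "\\1", regmatches(line, m))
      value <- substring(line, attr(m, "match.length") + 1L)
      fields[[length(fields) + 1L]] <- list(tag = cur_tag, value = value)
    } else if (grepl("^\\s+\\S", line) && !is.null(cur_tag)) {
      j <- length(fields)
      fields[[j]]$value <- paste(fields[[j]]$value, trimws(line))
    } else {
      stop(sprintf("malformed MEDLINE line %d: %s", i, line), call. = FALSE)
    }
  }
  flush_record()

  skipped <- c(no_abstract = 0L, no_title = 0L, no_pmid = 0L, no_year = 0L)
  docs <- vector("list", length(records))
  for (r in seq_along(records)) {
    rec <- records[[r]]
    tags <- vapply(rec, `[[`, character(1), "tag")
    vals <- vapply(rec, `[[`, character(1), "value")
    get1 <- function(tag) {
      hit <- which(tags == tag)
      if (length(hit)) trimws(vals[hit[1L]]) else NA_character_
    }
    ab_hits <- which(tags == "AB")
    abstract <- if (length(ab_hits)) {
      trimws(paste(vals[ab_hits], collapse = " "))
    } else {
      NA_character_
    }
    pmid <- get1("PMID")
    title <- get1("TI")
    dp <- get1("DP")
    year <- if (!is.na(dp)) {
      m <- regmatches(dp, regexpr("\\b[0-9]{4}\\b", dp))
      if (length(m)) as.integer(m) else NA_integer_
    } else {
      NA_integer_
    }
    if (is.na(abstract) || !nzchar(abstract)) {
      skipped["no_abstract"] <- skipped["no_abstract"] + 1L
    } else if (is.na(title)) {
      skipped["no_title"] <- skipped["no_title"] + 1L
    } else if (is.na(pmid)) {
      skipped["no_pmid"] <- skipped["no_pmid"] + 1L
    } else if (is.na(year)) {
      skipped["no_year"] <- skipped["no_year"] + 1L
    } else {
      docs[[r]] <- data.frame(
        record_id = pmid, title = title, abstract = abstract,
        year = year, slice_index = NA_integer_,
        stringsAsFactors = FALSE
      )
    }
  }
  docs <- docs[!vapply(docs, is.null, logical(1))]
  documents <- if (length(docs)) {
    do.call(rbind, docs)
  } else {
    data.frame(
      record_id = character(), title = character(), abstract = character(),
      year = integer(), slice_index = integer(), stringsAsFactors = FALSE
    )
  }
  rownames(documents) <- NULL
  list(documents = documents, skipped = skipped,
       n_records = length(records))
}

#' Time-slice configuration
#'
#' A set of inclusive, non-overlapping, strictly ascending publication-year
#' ranges.  Ranges need not be contiguous; years falling outside every
#' range are dropped by [assign_slices()].
#'
#' @param start_years,end_years integer vectors of equal length giving the
#'   inclusive bounds of each slice.
#' @return an object of class `slice_config` (data.frame with columns
#'   `start_year`, `end_year`).
#' @seealso [default_slice_config()] for the 16-slice scheme used for the
#'   ginseng corpus.
#' @export
slice_config <- function(start_years, end_years) {
  stopifnot(
    length(start_years) == length(end_years),
    length(start_years) >= 2L,
    all(end_years >= start_years)
  )
  if (any(start_years[-1L] <= end_years[-length(end_years)])) {
    stop("slice ranges must be non-overlapping and strictly ascending")
  }
  structure(
    data.frame(start_year = as.integer(start_years),
               end_year = as.integer(end_years)),
    class = c("slice_config", "data.frame")
  )
}

#' The 16-slice scheme for the 1975-2017 ginseng corpus
#'
#' Four multi-year slices covering 1975-2005 (so that early slices hold
#' roughly comparable document counts, about 400 each) followed by one
#' slice per year 2006-2017.
#'
#' @return a [slice_config()] with 16 ranges.
#' @export
default_slice_config <- function() {
  slice_config(
    start_years = c(1975L, 1996L, 2001L, 2004L, 2006:2017),
    end_years   = c(1995L, 2000L, 2003L, 2005L, 2006:2017)
  )
}

#' Assign documents to time slices
#'
#' Sets `slice_index` to the (1-based) index of the unique range containing
#' each document's publication year.  Documents outside every range are
#' dropped and counted, not treated as an error.
#'
#' @param docs document data.frame from [parse_medline()].
#' @param cfg a [slice_config()].
#' @return list with `documents` (slice_index filled in, out-of-range rows
#'   removed), `dropped` (count of out-of-range documents) and `n_slices`.
#' @export
assign_slices <- function(docs, cfg) {
  stopifnot(inherits(cfg, "slice_config"), !anyNA(docs$year))
  idx <- rep(NA_integer_, nrow(docs))
  for (s in seq_len(nrow(cfg))) {
    hit <- docs$year >= cfg$start_year[s] & docs$year <= cfg$end_year[s]
    idx[hit] <- s
  }
  keep <- !is.na(idx)
  out <- docs[keep, , drop = FALSE]
  out$slice_index <- idx[keep]
  rownames(out) <- NULL
  list(documents = out, dropped = sum(!keep), n_slices = nrow(cfg))
}

#' Sparse per-slice bag-of-words corpus
#'
#' The container every modelling stage consumes: an ordered vocabulary and,
#' per time slice, a list of sparse documents.  Word indices are 0-based,
#' matching the on-disk exchange format.
#'
#' @param vocab character vector of length `V`; `vocab[i + 1]` is the word
#'   with index `i`.
#' @param slices list of length `T`; `slices[[t]]` is a list of documents,
#'   each a list with integer vectors `idx` (0-based word indices, strictly
#'   increasing) and `cnt` (counts >= 1) of equal length.
#' @param doc_ids optional list parallel to `slices` with one id per
#'   document (kept through filtering for auditability).
#' @return an object of class `corpus_matrix`.
#' @export
corpus_matrix <- function(vocab, slices, doc_ids = NULL) {
  m <- structure(
    list(vocab = as.character(vocab), slices = slices, doc_ids = doc_ids),
    class = "corpus_matrix"
  )
  validate_corpus_matrix(m)
  m
}

validate_corpus_matrix <- function(m) {
  V <- length(m$vocab)
  for (t in seq_along(m$slices)) {
    for (doc in m$slices[[t]]) {
      stopifnot(
        length(doc$idx) == length(doc$cnt),
        length(doc$idx) >= 1L,
        all(doc$idx >= 0L), all(doc$idx < V),
        !anyDuplicated(doc$idx),
        all(doc$cnt >= 1L)
      )
    }
  }
  invisible(m)
}

#' @export
print.corpus_matrix <- function(x, ...) {
  nd <- vapply(x$slices, length, integer(1))
  cat(sprintf(
    "corpus_matrix: V = %d words, T = %d slices, %d documents, %d tokens\n",
    length(x$vocab), length(x$slices), sum(nd), corpus_total_tokens(x)
  ))
  invisible(x)
}

corpus_n_docs <- function(m) sum(vapply(m$slices, length, integer(1)))

corpus_total_tokens <- function(m) {
  sum(vapply(
    m$slices,
    function(sl) sum(vapply(sl, function(d) sum(d$cnt), numeric(1))),
    numeric(1)
  ))
}

# V-vector of summed counts over the whole corpus (1-based positions).
corpus_word_totals <- function(m) {
  tot <- numeric(length(m$vocab))
  for (sl in m$slices) {
    for (d in sl) tot[d$idx + 1L] <- tot[d$idx + 1L] + d$cnt
  }
  tot
}

# V-vector of document frequencies (number of docs containing each word).
corpus_doc_freq <- function(m) {
  df <- integer(length(m$vocab))
  for (sl in m$slices) {
    for (d in sl) df[d$idx + 1L] <- df[d$idx + 1L] + 1L
  }
  df
}

#' Write / read the sparse corpus exchange format
#'
#' Three plain-text files under a common prefix:
#' \describe{
#'   \item{`<prefix>-mult.dat`}{one document per line, slices in order:
#'     `"U idx1:cnt1 ... idxU:cntU"` with `U` the number of unique words
#'     and 0-based word indices.}
#'   \item{`<prefix>-seq.dat`}{first line the slice count `T`, then one
#'     line per slice with its document count.}
#'   \item{`<prefix>-vocab.dat`}{one word per line, in index order.}
#' }
#'
#' @param m a [corpus_matrix()].
#' @param prefix path prefix for the three files.
#' @return `write_corpus` returns the three paths invisibly; `read_corpus`
#'   returns the reconstructed `corpus_matrix`.  Reading fails with a
#'   format error if the per-slice counts in the seq file do not sum to the
#'   number of document lines.
#' @export
write_corpus <- function(m, prefix) {
  validate_corpus_matrix(m)
  paths <- corpus_paths(prefix)
  doc_lines <- unlist(lapply(m$slices, function(sl) {
    vapply(sl, function(d) {
      paste(length(d$idx), paste(d$idx, d$cnt, sep = ":", collapse = " "))
    }, character(1))
  }), use.names = FALSE)
  writeLines(doc_lines, paths$mult)
  writeLines(
    as.character(c(length(m$slices),
                   vapply(m$slices, length, integer(1)))),
    paths$seq
  )
  writeLines(m$vocab, paths$vocab)
  invisible(paths)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(prefix) {
  paths <- corpus_paths(prefix)
  for (p in paths) {
    if (!file.exists(p)) stop("corpus file not found: ", p, call. = FALSE)
  }
  vocab <- readLines(paths$vocab, warn = FALSE)
  seq_lines <- as.integer(readLines(paths$seq, warn = FALSE))
  T_ <- seq_lines[1L]
  per_slice <- seq_lines[-1L]
  if (length(per_slice) != T_) {
    stop("corpus format error: seq file declares ", T_, " slices but lists ",
         length(per_slice), call. = FALSE)
  }
  doc_lines <- readLines(paths$mult, warn = FALSE)
  doc_lines <- doc_lines[nzchar(doc_lines)]
  if (sum(per_slice) != length(doc_lines)) {
    stop("corpus format error: seq file counts sum to ", sum(per_slice),
         " but main file has ", length(doc_lines), " documents",
         call. = FALSE)
  }
  parse_doc <- function(line) {
    parts <- strsplit(trimws(line), "\\s+")[[1L]]
    u <- as.integer(parts[1L])
    pairs <- parts[-1L]
    if (length(pairs) != u) {
      stop("corpus format error: document declares ", u, " words but has ",
           length(pairs), call. = FALSE)
    }
    ic <- do.call(rbind, strsplit(pairs, ":", fixed = TRUE))
    list(idx = as.integer(ic[, 1L]), cnt = as.integer(ic[, 2L]))
  }
  docs <- lapply(doc_lines, parse_doc)
  bounds <- cumsum(c(0L, per_slice))
  slices <- lapply(seq_len(T_), function(t) {
    docs[seq.int(bounds[t] + 1L, length.out = per_slice[t])]
  })
  corpus_matrix(vocab, slices)
}

corpus_paths <- function(prefix) {
  list(
    mult = paste0(prefix, "-mult.dat"),
    seq = paste0(prefix, "-seq.dat"),
    vocab = paste0(prefix, "-vocab.dat")
  )
}
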