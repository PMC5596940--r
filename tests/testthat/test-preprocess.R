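test_that("tokenize_text splits on punctuation/hyphens and applies the drop rules", {
  expect_equal(
    tokenize_text("Ginseng's anti-cancer effects.", stopwords = character())[[1L]],
    c("ginseng", "anti", "cancer", "effects")
  )
  expect_equal(
    tokenize_text("p38 and NF-kappaB", stopwords = "and")[[1L]],
    c("p38", "nf", "kappab")
  )
  expect_equal(tokenize_text("", stopwords = character())[[1L]], character(0))
  expect_equal(tokenize_text("42 17 9", stopwords = character())[[1L]],
               character(0))
})

make_docs <- function(texts, slices) {
  data.frame(
    record_id = as.character(seq_along(texts)), title = "",
    abstract = texts, year = 2000L, slice_index = slices
  )
}

test_that("build_matrix counts dictionary-qualified stems only", {
  dict <- build_dictionary(list(x = c("heart", "attack")))
  docs <- make_docs("heart heart attack", 1L)
  cfg <- pipeline_config(min_total_freq = 1L, tfidf_quantile = NA,
                         stopwords = character(0))
  m <- build_matrix(docs, dict, cfg, n_slices = 1L)
  expect_equal(m$vocab, c("attack", "heart"))
  expect_equal(m$slices[[1L]][[1L]],
               list(idx = c(0L, 1L), cnt = c(1L, 2L)))
  # narrower dictionary narrows the vocabulary
  dict2 <- build_dictionary(list(x = "heart"))
  m2 <- build_matrix(docs, dict2, cfg, n_slices = 1L)
  expect_equal(m2$vocab, "heart")
})

test_that("documents emptied by the dictionary are dropped and reported; empty slices error", {
  dict <- build_dictionary(list(x = "heart"))
  cfg <- pipeline_config(min_total_freq = 1L, tfidf_quantile = NA,
                         stopwords = character(0))
  docs <- make_docs(c("heart disease", "unrelated words"), c(1L, 1L))
  m <- build_matrix(docs, dict, cfg, n_slices = 1L)
  expect_equal(attr(m, "drop_report")$dropped_empty_after_dictionary, 1L)
  docs2 <- make_docs(c("heart", "nothing relevant"), c(1L, 2L))
  expect_error(build_matrix(docs2, dict, cfg, n_slices = 2L), "slice")
})

test_that("filter_total_frequency removes rare words and reindexes densely", {
  m <- corpus_matrix(
    c("a", "b", "c"),
    list(list(list(idx = c(0L, 1L), cnt = c(1L, 3L)),
              list(idx = c(1L, 2L), cnt = c(1L, 2L))))
  )
  f <- filter_total_frequency(m, 2L)
  expect_equal(f$vocab, c("b", "c"))
  expect_equal(f$slices[[1L]][[1L]], list(idx = 0L, cnt = 3L))
  expect_equal(f$slices[[1L]][[2L]], list(idx = c(0L, 1L), cnt = c(1L, 2L)))
  # min_total = 1 is the identity
  expect_identical(filter_total_frequency(m, 1L), m)
})

test_that("a word present in every document gets tf-idf score 0 and is pruned", {
  m <- corpus_matrix(
    c("everywhere", "rare"),
    list(list(list(idx = c(0L, 1L), cnt = c(1L, 1L)),
              list(idx = 0L, cnt = 2L),
              list(idx = c(0L, 1L), cnt = c(3L, 1L))))
  )
  s <- tfidf_scores(m)
  expect_equal(unname(s["everywhere"]), 0)
  f <- filter_tfidf(m, quantile = 0.25)
  expect_false("everywhere" %in% f$vocab)
})

test_that("quantile 0 with distinct positive scores removes exactly the minimum", {
  set.seed(5)
  repeat {
    m <- random_corpus(V = 8L, T_ = 2L, docs_per_slice = 3L)
    s <- tfidf_scores(m)
    if (all(s > 0) && !anyDuplicated(s)) break
  }
  f <- filter_tfidf(m, quantile = 0)
  expect_setequal(f$vocab, names(s)[s > min(s)])
})

test_that("filters agree with the brute-force oracle on randomized corpora", {
  set.seed(11)
  for (rep in 1:40) {
    m <- random_corpus(V = sample(5:15, 1L), T_ = sample(2:3, 1L),
                       docs_per_slice = sample(2:4, 1L))
    min_total <- sample(1:3, 1L)
    q <- stats::runif(1L, 0, 0.6)
    expected <- oracle_filter_words(m, min_total, q)
    f <- filter_tfidf(filter_total_frequency(m, min_total), q, reference = m)
    expect_setequal(f$vocab, expected)
  }
})

test_that("the filter pipeline never grows the corpus and leaves no empty rows or docs", {
  set.seed(13)
  for (rep in 1:10) {
    m <- random_corpus(V = 12L, T_ = 3L, docs_per_slice = 4L)
    f <- filter_tfidf(filter_total_frequency(m, 2L), 0.25, reference = m)
    expect_lte(length(f$vocab), length(m$vocab))
    expect_lte(corpus_total_tokens(f), corpus_total_tokens(m))
    expect_lte(corpus_n_docs(f), corpus_n_docs(m))
    if (length(f$vocab)) {
      expect_true(all(corpus_word_totals(f) >= 1))
      for (sl in f$slices) for (d in sl) expect_gte(length(d$idx), 1L)
    }
  }
})

test_that("build_matrix output is invariant to document order within slices", {
  dict <- build_dictionary(list(x = c(
    "heart attack", "renal failure", "memory", "apoptosis", "gene"
  )))
  texts <- c("heart attack and memory", "renal failure apoptosis",
             "gene gene heart", "memory of apoptosis heart")
  cfg <- pipeline_config(min_total_freq = 2L, tfidf_quantile = 0.25)
  m1 <- build_matrix(make_docs(texts, rep(1L, 4)), dict, cfg, n_slices = 1L)
  m2 <- build_matrix(make_docs(rev(texts), rep(1L, 4)), dict, cfg,
                     n_slices = 1L)
  expect_identical(m1$vocab, m2$vocab)
  sorted_docs <- function(m) {
    lapply(m$slices, function(sl) {
      sl[order(vapply(sl, function(d) paste(d$idx, d$cnt, collapse = ";"),
                      character(1)))]
    })
  }
  expect_identical(sorted_docs(m1), sorted_docs(m2))
})
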