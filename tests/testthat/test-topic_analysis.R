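# A model with hand-set natural parameters: 2 topics, 3 words, 2 slices.
toy_model <- function(b1, b2, vocab = c("a", "b", "c")) {
  model <- structure(
    list(K = 2L, V = length(vocab), T = ncol(b1), alpha = 0.1,
         sigma2 = 0.005, sigma0_2 = 1, vocab = vocab,
         b = list(b1, b2)),
    class = "dtm_model"
  )
  biodtm:::model_refresh_phi(model)
}

test_that("top_words ranks by probability with index tie-break", {
  b1 <- cbind(log(c(0.5, 0.3, 0.2)), log(c(0.2, 0.3, 0.5)))
  b2 <- cbind(c(0, 0, 0), c(1, 1, 0))  # exact tie between indices 1 and 2
  model <- toy_model(b1, b2)
  expect_equal(top_words(model, 1L, 1L, 2L), c("a", "b"))
  expect_equal(top_words(model, 1L, 2L, 2L), c("c", "b"))
  expect_equal(top_words(model, 2L, 2L, 2L), c("a", "b"))  # tie -> low index
  # n >= V returns the whole vocabulary as a permutation
  expect_setequal(top_words(model, 1L, 1L, 10L), model$vocab)
})

test_that("overall_top_words averages phi over slices (brute-force checked)", {
  set.seed(71)
  b1 <- matrix(rnorm(12), 4L, 3L)
  b2 <- matrix(rnorm(12), 4L, 3L)
  model <- toy_model(b1, b2, vocab = c("a", "b", "c", "d"))
  model$T <- 3L
  # independent recomputation
  mean_phi <- rowMeans(vapply(1:3, function(t) topic_distribution(model, 1L, t),
                              numeric(4L)))
  expected <- model$vocab[order(-mean_phi, seq_len(4L))]
  expect_equal(overall_top_words(model, 1L, 4L), expected)
  # constant-over-t phi: any single-slice ranking matches
  bc <- matrix(rep(c(0.9, -0.3, 0.1, -0.7), 3L), 4L, 3L)
  model_c <- toy_model(bc, bc, vocab = c("a", "b", "c", "d"))
  expect_equal(overall_top_words(model_c, 1L, 4L),
               top_words(model_c, 1L, 2L, 4L))
})

test_that("topic_strength is the token-weighted share and normalizes per slice", {
  set.seed(81)
  m <- random_corpus(V = 9L, T_ = 3L, docs_per_slice = 4L)
  f <- fit_dtm(m, fit_config(K = 3L, max_iter = 4L, seed = 2L))
  s <- topic_strength(f$model, f$posterior, m)
  expect_equal(colSums(unclass(s)), rep(1, 3L), tolerance = 1e-10)
  expect_true(all(s >= 0))
  # K = 1 forces strength 1 everywhere
  f1 <- fit_dtm(m, fit_config(K = 1L, max_iter = 2L))
  s1 <- topic_strength(f1$model, f1$posterior, m)
  expect_equal(as.vector(unclass(s1)), rep(1, 3L), tolerance = 1e-12)
  # direct recomputation from responsibilities and counts
  expected <- matrix(0, 3L, 3L)
  tok <- numeric(3L)
  for (d in seq_along(f$posterior$resp)) {
    rd <- f$posterior$resp[[d]]
    t <- f$posterior$doc_slice[d]
    expected[, t] <- expected[, t] + colSums(rd$r * rd$cnt)
    tok[t] <- tok[t] + sum(rd$cnt)
  }
  expect_equal(unclass(s), sweep(expected, 2L, tok, "/"), tolerance = 1e-12)
})

test_that("a planted dominant topic per slice is recovered by argmax strength", {
  # hand-planted dominance: in slice t, 85% of every document's mass sits
  # on topic planted[t], so the slice's true strength leader is known
  set.seed(91)
  spec <- synthetic_spec(K = 2L, V = 40L, T_ = 4L, docs_per_slice = 30L,
                         mean_doc_length = 40, drift_sd = 0.05, seed = 19L)
  truth <- sample_ground_truth(spec)
  planted <- c(1L, 2L, 1L, 2L)
  slices <- lapply(seq_len(4L), function(t) {
    theta <- if (planted[t] == 1L) c(0.85, 0.15) else c(0.15, 0.85)
    lapply(seq_len(30L), function(j) {
      z <- sample.int(2L, 40L, replace = TRUE, prob = theta)
      wc <- integer(40L)
      for (k in 1:2) {
        nk <- sum(z == k)
        if (nk > 0L) {
          w <- sample.int(40L, nk, replace = TRUE,
                          prob = truth$phi[[k]][, t])
          wc <- wc + tabulate(w, nbins = 40L)
        }
      }
      pos <- which(wc > 0L)
      list(idx = pos - 1L, cnt = wc[pos])
    })
  })
  m <- corpus_matrix(truth$vocab, slices)
  f <- fit_dtm(m, fit_config(K = 2L, max_iter = 30L, seed = 19L))
  s <- topic_strength(f$model, f$posterior, m)
  # align fitted topics to truth before comparing argmaxes
  mt <- matched_mean_tv(truth$phi, f$model$phi)
  recovered <- apply(unclass(s), 2L, which.max)
  aligned <- match(recovered, mt$perm)
  expect_gte(mean(aligned == planted), 0.9)
})

test_that("export_topic_table writes deterministic summary and long tables", {
  m <- random_corpus(V = 8L, T_ = 3L, docs_per_slice = 3L)
  f <- fit_dtm(m, fit_config(K = 2L, max_iter = 3L, seed = 6L))
  path <- file.path(tempdir(), "topics.csv")
  res <- export_topic_table(f$model, 3L, path)
  summary_df <- utils::read.csv(res$summary)
  long_df <- utils::read.csv(res$long)
  expect_equal(nrow(summary_df), 2L)
  expect_equal(nrow(long_df), 2L * 3L * 3L)
  # probabilities non-increasing within each (topic, slice)
  for (grp in split(long_df, interaction(long_df$topic, long_df$slice))) {
    expect_true(all(diff(grp$probability[order(grp$rank)]) <= 0))
  }
  # byte-identical re-export
  first <- readLines(res$summary)
  export_topic_table(f$model, 3L, path)
  expect_identical(readLines(res$summary), first)
})

test_that("strength CSV round-trips", {
  s <- structure(matrix(c(0.2, 0.8, 0.5, 0.5, 0.9, 0.1), 2L, 3L),
                 class = c("topic_strength", "matrix"))
  path <- tempfile(fileext = ".csv")
  write_strengths(s, path, slice_labels = c("1975-1995", "1996-2000", "2001"))
  s2 <- read_strengths(path)
  expect_equal(unclass(s2), unclass(s), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(s2, "slice_labels"), c("1975-1995", "1996-2000", "2001"))
})
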