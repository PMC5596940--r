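test_that("init_model is seed-deterministic and uniform for flat corpora", {
  m <- random_corpus(V = 8L, T_ = 3L, docs_per_slice = 3L)
  cfg <- fit_config(K = 3L, seed = 7L)
  m1 <- init_model(m, cfg)
  m2 <- init_model(m, cfg)
  expect_identical(m1$b, m2$b)
  expect_false(identical(m1$b, init_model(m, fit_config(K = 3L, seed = 8L))$b))
  # uniform counts, K = 1 (no noise) -> uniform phi
  flat <- corpus_matrix(
    c("a", "b", "c", "d"),
    list(list(list(idx = 0:3, cnt = rep(2L, 4L))))
  )
  mu <- init_model(flat, fit_config(K = 1L))
  expect_equal(mu$phi[[1L]][, 1L], rep(0.25, 4L), tolerance = 1e-12)
  expect_error(init_model(flat, fit_config(K = 100L)), "token")
})

test_that("e_step: K = 1 forces unit responsibilities and gamma = alpha + length", {
  m <- random_corpus(V = 6L, T_ = 2L, docs_per_slice = 3L)
  model <- init_model(m, fit_config(K = 1L, alpha = 0.3))
  es <- e_step(model, m)
  lens <- unlist(lapply(m$slices, function(sl)
    vapply(sl, function(d) sum(d$cnt), numeric(1))))
  expect_equal(as.vector(es$gamma), 0.3 + lens, tolerance = 1e-10)
  for (rd in es$resp) expect_equal(as.vector(rd$r), rep(1, length(rd$idx)))
})

test_that("e_step responsibilities normalize and suffstats conserve observed counts", {
  set.seed(21)
  m <- random_corpus(V = 10L, T_ = 3L, docs_per_slice = 4L)
  model <- init_model(m, fit_config(K = 3L, seed = 2L))
  es <- e_step(model, m)
  for (rd in es$resp) {
    expect_equal(rowSums(rd$r), rep(1, nrow(rd$r)), tolerance = 1e-10)
  }
  # conservation recomputed directly from the returned responsibilities
  obs <- lapply(seq_along(m$slices), function(t) {
    x <- numeric(length(m$vocab))
    for (d in m$slices[[t]]) x[d$idx + 1L] <- x[d$idx + 1L] + d$cnt
    x
  })
  total <- Reduce(`+`, es$suffstats)
  for (t in seq_along(m$slices)) {
    expect_equal(total[, t], obs[[t]], tolerance = 1e-8)
  }
  # identical documents get identical posteriors
  twin <- corpus_matrix(m$vocab, list(list(
    list(idx = c(0L, 2L), cnt = c(2L, 1L)),
    list(idx = c(0L, 2L), cnt = c(2L, 1L))
  )))
  model1 <- init_model(twin, fit_config(K = 2L, seed = 5L))
  es1 <- e_step(model1, twin)
  expect_equal(es1$gamma[1L, ], es1$gamma[2L, ], tolerance = 1e-12)
})

test_that("m_step limit behaviors: per-slice MLE, pooled MLE, single-slice closed form", {
  set.seed(31)
  m <- random_corpus(V = 9L, T_ = 3L, docs_per_slice = 5L)
  # sigma2 huge: independent multinomial MLE per slice
  f_loose <- fit_dtm(m, fit_config(K = 1L, sigma2 = 1e6, sigma0_2 = 1e6,
                                   max_iter = 10L))
  for (t in seq_along(m$slices)) {
    expect_lt(tv_distance(f_loose$model$phi[[1L]][, t],
                          slice_empirical(m, t)), 1e-3)
  }
  # sigma2 tiny: chain frozen at the pooled distribution
  f_stiff <- fit_dtm(m, fit_config(K = 1L, sigma2 = 1e-8, sigma0_2 = 1e6,
                                   max_iter = 10L))
  pooled <- pooled_empirical(m)
  for (t in seq_along(m$slices)) {
    expect_lt(tv_distance(f_stiff$model$phi[[1L]][, t], pooled), 1e-3)
  }
  drift <- max(vapply(2:3, function(t) {
    tv_distance(f_stiff$model$phi[[1L]][, t], f_stiff$model$phi[[1L]][, t - 1L])
  }, numeric(1)))
  expect_lt(drift, 1e-6)
  # single slice, prior off: empirical frequencies exactly
  m1 <- corpus_matrix(m$vocab, m$slices[1L])
  f_one <- fit_dtm(m1, fit_config(K = 1L, sigma0_2 = 1e6, max_iter = 5L))
  expect_lt(tv_distance(f_one$model$phi[[1L]][, 1L], slice_empirical(m, 1L)),
            1e-3)
})

test_that("sigma2 -> infinity reproduces independent per-slice fits (K = 2)", {
  set.seed(61)
  m <- random_corpus(V = 8L, T_ = 3L, docs_per_slice = 6L)
  cfg <- fit_config(K = 2L, sigma2 = 1e6, sigma0_2 = 1e6, max_iter = 20L,
                    seed = 3L)
  init <- init_model(m, cfg)
  f_joint <- fit_dtm(m, cfg, init = init)
  for (t in seq_along(m$slices)) {
    m_t <- corpus_matrix(m$vocab, m$slices[t])
    init_t <- init
    init_t$T <- 1L
    init_t$b <- lapply(init$b, function(B) B[, t, drop = FALSE])
    f_t <- fit_dtm(m_t, cfg, init = init_t)
    for (k in 1:2) {
      expect_lt(tv_distance(f_joint$model$phi[[k]][, t],
                            f_t$model$phi[[k]][, 1L]), 1e-2)
    }
  }
})

test_that("m_step output chains are mean-centered", {
  m <- random_corpus(V = 7L, T_ = 3L, docs_per_slice = 3L)
  f <- fit_dtm(m, fit_config(K = 2L, max_iter = 3L))
  for (B in f$model$b) {
    expect_equal(colMeans(B), rep(0, ncol(B)), tolerance = 1e-10)
  }
})

test_that("the tracked EM objective is non-decreasing", {
  set.seed(41)
  for (rep in 1:5) {
    m <- random_corpus(V = sample(6:12, 1L), T_ = sample(2:3, 1L),
                       docs_per_slice = sample(3:5, 1L))
    f <- fit_dtm(m, fit_config(K = sample(1:3, 1L), max_iter = 8L,
                               seed = rep))
    if (length(f$trace) > 1L) {
      rel <- diff(f$trace) / abs(f$trace[-length(f$trace)])
      expect_gte(min(rel), -1e-6)
    }
  }
})

test_that("relabeling topics at init permutes the fitted output", {
  set.seed(51)
  m <- random_corpus(V = 8L, T_ = 2L, docs_per_slice = 4L)
  cfg <- fit_config(K = 3L, max_iter = 5L, seed = 9L)
  init <- init_model(m, cfg)
  perm <- c(2L, 3L, 1L)
  init_p <- init
  init_p$b <- init$b[perm]
  f <- fit_dtm(m, cfg, init = init)
  f_p <- fit_dtm(m, cfg, init = init_p)
  for (k in 1:3) {
    expect_equal(f_p$model$b[[k]], f$model$b[[perm[k]]], tolerance = 1e-8)
  }
})

test_that("fit is deterministic given the seed", {
  m <- random_corpus(V = 8L, T_ = 2L, docs_per_slice = 3L)
  cfg <- fit_config(K = 2L, max_iter = 4L, seed = 17L)
  f1 <- fit_dtm(m, cfg)
  f2 <- fit_dtm(m, cfg)
  expect_identical(f1$model$b, f2$model$b)
  expect_identical(f1$trace, f2$trace)
})

test_that("topic_distribution: uniform at b = 0, shift-invariant, normalized", {
  m <- random_corpus(V = 4L, T_ = 2L, docs_per_slice = 2L)
  model <- init_model(m, fit_config(K = 2L, seed = 1L))
  model$b[[1L]][] <- 0
  model <- biodtm:::model_refresh_phi(model)
  expect_equal(topic_distribution(model, 1L, 1L), rep(0.25, 4L))
  shifted <- model
  shifted$b[[2L]] <- shifted$b[[2L]] + 3.7
  shifted <- biodtm:::model_refresh_phi(shifted)
  expect_equal(topic_distribution(shifted, 2L, 2L),
               topic_distribution(model, 2L, 2L), tolerance = 1e-12)
  expect_equal(sum(topic_distribution(model, 2L, 1L)), 1, tolerance = 1e-10)
  expect_error(topic_distribution(model, 3L, 1L), "out of range")
  expect_error(topic_distribution(model, 1L, 5L), "out of range")
})

test_that("model artifacts round-trip through write_model/read_model", {
  m <- random_corpus(V = 6L, T_ = 2L, docs_per_slice = 3L)
  cfg <- fit_config(K = 2L, max_iter = 3L, seed = 4L)
  f <- fit_dtm(m, cfg)
  dir <- tempfile()
  write_model(f, dir, cfg)
  model2 <- read_model(dir)
  expect_equal(model2$b, f$model$b, tolerance = 1e-12)
  expect_identical(model2$vocab, f$model$vocab)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$K, 2L)
  expect_equal(manifest$seed, 4L)
})
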