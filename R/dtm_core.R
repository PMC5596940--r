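#' Fit configuration for the dynamic topic model
#'
#' @param K number of topics (default 20, the setting used for the ginseng
#'   corpus).
#' @param alpha symmetric Dirichlet concentration of the document-topic
#'   mixtures (default 0.1; static over time).
#' @param sigma2 drift variance of the Gaussian random walk that ties each
#'   topic's natural parameters across adjacent slices (default 0.005).
#'   Large values decouple the slices; values near zero freeze the topic
#'   over time.
#' @param sigma0_2 variance of the zero-mean Gaussian prior on the first
#'   slice (default 1).
#' @param max_iter maximum EM iterations (default 100).
#' @param conv_tol relative change of the tracked objective below which EM
#'   stops (default 1e-4).
#' @param e_tol,e_max_iter convergence tolerance (max absolute change of
#'   the variational Dirichlet parameters) and iteration cap of the
#'   per-document mean-field loop.
#' @param m_tol projected-gradient tolerance of the M-step optimizer.
#' @param m_max_iter iteration cap of the M-step optimizer per topic.
#' @param seed integer seed driving every stochastic choice (initial
#'   topic perturbations).
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(K = 20L, alpha = 0.1, sigma2 = 0.005, sigma0_2 = 1,
                       max_iter = 100L, conv_tol = 1e-4,
                       e_tol = 1e-6, e_max_iter = 100L,
                       m_tol = 1e-4, m_max_iter = 500L, seed = 1L) {
  stopifnot(K >= 1L, alpha > 0, sigma2 > 0, sigma0_2 > 0,
            max_iter >= 1L, conv_tol > 0, e_tol > 0, m_tol > 0)
  structure(
    list(K = as.integer(K), alpha = alpha, sigma2 = sigma2,
         sigma0_2 = sigma0_2, max_iter = as.integer(max_iter),
         conv_tol = conv_tol, e_tol = e_tol,
         e_max_iter = as.integer(e_max_iter), m_tol = m_tol,
         m_max_iter = as.integer(m_max_iter), seed = as.integer(seed)),
    class = "fit_config"
  )
}

# Recompute the per-topic, per-slice softmax caches from the natural
# parameters b.
model_refresh_phi <- function(model) {
  model$log_phi <- lapply(model$b, function(B) {
    sweep(B, 2L, apply(B, 2L, log_sum_exp), "-")
  })
  model$phi <- lapply(model$log_phi, exp)
  model
}

#' Initialize a dynamic topic model
#'
#' Every topic chain starts from the mean-centered log of the smoothed
#' corpus-wide word frequencies; for `K > 1` each topic additionally gets
#' seed-deterministic Gaussian noise (sd 0.1) to break symmetry, constant
#' across slices.  Identical seeds give bit-identical models.
#'
#' @param m a [corpus_matrix()].
#' @param cfg a [fit_config()].
#' @return an object of class `dtm_model`: fields `K`, `V`, `T`, `alpha`,
#'   `sigma2`, `sigma0_2`, `vocab`, `b` (list of `K` mean-centered `V x T`
#'   natural-parameter matrices) and cached `phi` / `log_phi`.
#' @export
init_model <- function(m, cfg) {
  stopifnot(inherits(cfg, "fit_config"))
  V <- length(m$vocab)
  T_ <- length(m$slices)
  total_tokens <- corpus_total_tokens(m)
  if (cfg$K > total_tokens) {
    stop("K = ", cfg$K, " exceeds the total token count ", total_tokens)
  }
  freq <- corpus_word_totals(m) + 1 / V
  base <- log(freq / sum(freq))
  base <- base - mean(base)
  set.seed(cfg$seed)
  b <- lapply(seq_len(cfg$K), function(k) {
    col <- if (cfg$K > 1L) base + stats::rnorm(V, sd = 0.1) else base
    col <- col - mean(col)
    matrix(col, nrow = V, ncol = T_)
  })
  model <- structure(
    list(K = cfg$K, V = V, T = T_, alpha = cfg$alpha, sigma2 = cfg$sigma2,
         sigma0_2 = cfg$sigma0_2, vocab = m$vocab, b = b),
    class = "dtm_model"
  )
  model_refresh_phi(model)
}

#' @export
print.dtm_model <- function(x, ...) {
  cat(sprintf("dtm_model: K = %d topics, V = %d words, T = %d slices\n",
              x$K, x$V, x$T))
  invisible(x)
}

#' Variational E-step
#'
#' For every document, runs mean-field coordinate ascent on the standard
#' LDA per-document posterior with the document's slice-specific topic-word
#' distributions held fixed: token responsibilities
#' `r[n, k] proportional to phi[k, t, w_n] * exp(digamma(gamma[k]))` and
#' Dirichlet updates `gamma[k] = alpha + sum_n count_n r[n, k]`, iterated
#' to `e_tol`.  Expected topic-word counts are accumulated into sufficient
#' statistics for the M-step.
#'
#' @param model a `dtm_model`.
#' @param m the [corpus_matrix()] it was built for (same `V` and `T`).
#' @param e_tol,e_max_iter inner-loop control (defaults from the model's
#'   typical [fit_config()] values).
#' @param gamma0 optional documents-by-K matrix of Dirichlet parameters to
#'   warm-start each document's mean-field loop (the previous EM
#'   iteration's `gamma`).  Warm-starting makes the EM objective provably
#'   non-decreasing: coordinate ascent resumed from the incumbent can only
#'   improve it, while a cold start can land on a different local optimum.
#' @return an object of class `dtm_posterior`: `gamma` (documents x K),
#'   `resp` (per document: `idx`, `cnt`, and the `n_unique x K`
#'   responsibility matrix), `doc_slice`, `suffstats` (list of `K` `V x T`
#'   expected-count matrices), `N` (`K x T` expected token totals),
#'   `e_objective` (the document terms of the variational bound) and
#'   `e_objective_nonword` (the same bound without the
#'   `E[log p(w | z, phi)]` term, whose counterpart lives in the M-step
#'   objective).
#' @export
e_step <- function(model, m, e_tol = 1e-6, e_max_iter = 100L,
                   gamma0 = NULL) {
  stopifnot(inherits(model, "dtm_model"),
            length(m$vocab) == model$V,
            length(m$slices) == model$T)
  K <- model$K
  alpha <- model$alpha
  suffstats <- lapply(seq_len(K), function(k) matrix(0, model$V, model$T))
  n_docs <- corpus_n_docs(m)
  gamma_all <- matrix(NA_real_, n_docs, K)
  resp <- vector("list", n_docs)
  doc_slice <- integer(n_docs)
  e_obj <- 0
  e_obj_nonword <- 0
  const_theta <- lgamma(K * alpha) - K * lgamma(alpha)
  d_i <- 0L
  for (t in seq_along(m$slices)) {
    lphi_t <- vapply(model$log_phi, function(L) L[, t], numeric(model$V))
    lphi_t <- matrix(lphi_t, nrow = model$V, ncol = K)
    for (doc in m$slices[[t]]) {
      d_i <- d_i + 1L
      doc_slice[d_i] <- t
      w <- doc$idx + 1L
      cnt <- doc$cnt
      lp <- lphi_t[w, , drop = FALSE]
      gam <- if (is.null(gamma0)) {
        rep(alpha + sum(cnt) / K, K)
      } else {
        gamma0[d_i, ]
      }
      r <- NULL
      for (it in seq_len(e_max_iter)) {
        lr <- sweep(lp, 2L, digamma(gam), "+")
        lr <- lr - apply(lr, 1L, log_sum_exp)
        r <- exp(lr)
        gam_new <- alpha + colSums(r * cnt)
        delta <- max(abs(gam_new - gam))
        gam <- gam_new
        if (delta < e_tol) break
      }
      for (k in seq_len(K)) {
        suffstats[[k]][w, t] <- suffstats[[k]][w, t] + cnt * r[, k]
      }
      gamma_all[d_i, ] <- gam
      resp[[d_i]] <- list(idx = doc$idx, cnt = cnt, r = r)
      # variational bound, document terms
      eq_lt <- digamma(gam) - digamma(sum(gam))
      word_term <- sum((r * cnt) * lp)
      ent_z <- -sum(cnt * ifelse(r > 0, r * log(r), 0))
      nonword <- const_theta + sum((alpha - 1) * eq_lt) +
        sum(cnt * (r %*% eq_lt)) -
        (lgamma(sum(gam)) - sum(lgamma(gam)) + sum((gam - 1) * eq_lt)) +
        ent_z
      e_obj <- e_obj + nonword + word_term
      e_obj_nonword <- e_obj_nonword + nonword
    }
  }
  N <- t(vapply(suffstats, colSums, numeric(model$T)))
  N <- matrix(N, nrow = K, ncol = model$T)
  structure(
    list(gamma = gamma_all, resp = resp, doc_slice = doc_slice,
         suffstats = suffstats, N = N,
         e_objective = e_obj, e_objective_nonword = e_obj_nonword),
    class = "dtm_posterior"
  )
}

# Penalized chain objective J_k for one topic (to be maximized) and its
# gradient, in the mean-centered parameterization: the likelihood term is
# invariant to per-slice constant shifts, so the optimization is restricted
# to mean-zero columns, which also enforces identifiability.
chain_objective <- function(v, n_mat, N_t, sigma2, sigma0_2) {
  B <- matrix(v, nrow = nrow(n_mat))
  B <- sweep(B, 2L, colMeans(B), "-")
  lse <- apply(B, 2L, log_sum_exp)
  ll <- sum(n_mat * B) - sum(N_t * lse)
  d <- B[, -1L, drop = FALSE] - B[, -ncol(B), drop = FALSE]
  pen <- sum(d^2) / (2 * sigma2) + sum(B[, 1L]^2) / (2 * sigma0_2)
  -(ll - pen)
}

chain_gradient <- function(v, n_mat, N_t, sigma2, sigma0_2) {
  V <- nrow(n_mat)
  T_ <- ncol(n_mat)
  B <- matrix(v, nrow = V)
  B <- sweep(B, 2L, colMeans(B), "-")
  lse <- apply(B, 2L, log_sum_exp)
  phi <- exp(sweep(B, 2L, lse, "-"))
  G <- n_mat - sweep(phi, 2L, N_t, "*")
  dpen <- matrix(0, V, T_)
  if (T_ > 1L) {
    d <- (B[, -1L, drop = FALSE] - B[, -T_, drop = FALSE]) / sigma2
    dpen[, -1L] <- dpen[, -1L, drop = FALSE] + d
    dpen[, -T_] <- dpen[, -T_, drop = FALSE] - d
  }
  dpen[, 1L] <- dpen[, 1L] + B[, 1L] / sigma0_2
  grad_B <- G - dpen                      # gradient of J
  grad_B <- sweep(grad_B, 2L, colMeans(grad_B), "-")  # project to centered
  -as.vector(grad_B)
}

#' MAP M-step over the topic chains
#'
#' For each topic `k`, maximizes the penalized chain objective
#' `J_k = sum_t n[k, t, ] . log softmax(b[k, t]) -
#' (1 / (2 sigma2)) sum_t ||b[k, t] - b[k, t - 1]||^2 -
#' (1 / (2 sigma0_2)) ||b[k, 1]||^2` by quasi-Newton (L-BFGS-B) ascent with
#' the analytic gradient
#' `n[k, t, ] - N[k, t] phi[k, t] - (chain difference terms)`, warm-started
#' at the current chain and restricted to mean-centered slices so the
#' softmax shift direction is pinned.
#'
#' @param model a `dtm_model`.
#' @param stats sufficient statistics from [e_step()] (its `suffstats`
#'   field, or a `dtm_posterior` object).
#' @param m_tol projected-gradient tolerance.
#' @param m_max_iter optimizer iteration cap per topic.
#' @return list with the updated `model` and `m_objective = sum_k J_k`.
#'   Errors (naming topic and slice) if the objective turns non-finite.
#' @export
m_step <- function(model, stats, m_tol = 1e-4, m_max_iter = 500L) {
  if (inherits(stats, "dtm_posterior")) stats <- stats$suffstats
  stopifnot(length(stats) == model$K)
  m_objective <- 0
  for (k in seq_len(model$K)) {
    n_mat <- stats[[k]]
    stopifnot(nrow(n_mat) == model$V, ncol(n_mat) == model$T)
    N_t <- colSums(n_mat)
    res <- stats::optim(
      par = as.vector(model$b[[k]]),
      fn = chain_objective, gr = chain_gradient,
      n_mat = n_mat, N_t = N_t,
      sigma2 = model$sigma2, sigma0_2 = model$sigma0_2,
      method = "L-BFGS-B",
      control = list(maxit = m_max_iter, pgtol = m_tol, factr = 10)
    )
    B <- matrix(res$par, nrow = model$V)
    B <- sweep(B, 2L, colMeans(B), "-")
    if (!all(is.finite(B)) || !is.finite(res$value)) {
      bad_t <- which(!apply(is.finite(B), 2L, all))[1L]
      if (is.na(bad_t)) bad_t <- 0L
      stop("non-finite M-step objective for topic ", k, ", slice ", bad_t)
    }
    model$b[[k]] <- B
    m_objective <- m_objective - res$value
  }
  list(model = model_refresh_phi(model), m_objective = m_objective)
}

#' Fit the dynamic topic model by variational EM
#'
#' Alternates [e_step()] and [m_step()] until the relative change of the
#' tracked objective — the variational bound's document terms (without the
#' word-likelihood term) plus the penalized chain objective `sum_k J_k` —
#' falls below `conv_tol`, or `max_iter` is reached.  Fully deterministic
#' given `cfg$seed`.
#'
#' @param m a [corpus_matrix()].
#' @param cfg a [fit_config()].
#' @param init optional `dtm_model` to start from (bypasses
#'   [init_model()]; used for warm starts and permutation tests).
#' @return list with `model` (the fitted `dtm_model`), `posterior` (a final
#'   `dtm_posterior` consistent with the returned model), `trace` (tracked
#'   objective per iteration, non-decreasing up to line-search round-off),
#'   `iterations` and `converged`.
#' @export
fit_dtm <- function(m, cfg = fit_config(), init = NULL) {
  stopifnot(inherits(cfg, "fit_config"))
  model <- if (is.null(init)) init_model(m, cfg) else model_refresh_phi(init)
  trace <- numeric(0)
  prev <- NA_real_
  prev_gamma <- NULL
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    es <- e_step(model, m, e_tol = cfg$e_tol, e_max_iter = cfg$e_max_iter,
                 gamma0 = prev_gamma)
    prev_gamma <- es$gamma
    ms <- m_step(model, es$suffstats, m_tol = cfg$m_tol,
                 m_max_iter = cfg$m_max_iter)
    model <- ms$model
    obj <- es$e_objective_nonword + ms$m_objective
    trace <- c(trace, obj)
    if (!is.na(prev) && abs(obj - prev) <= cfg$conv_tol * abs(prev)) {
      converged <- TRUE
      break
    }
    prev <- obj
  }
  posterior <- e_step(model, m, e_tol = cfg$e_tol,
                      e_max_iter = cfg$e_max_iter, gamma0 = prev_gamma)
  list(model = model, posterior = posterior, trace = trace,
       iterations = length(trace), converged = converged)
}

#' Topic-word distribution at one slice
#'
#' @param model a `dtm_model`.
#' @param k topic index in `[1, K]`.
#' @param t slice index in `[1, T]`.
#' @return the probability vector `phi[k, t]` over the vocabulary (cached
#'   softmax of the natural parameters).
#' @export
topic_distribution <- function(model, k, t) {
  stopifnot(inherits(model, "dtm_model"))
  if (k < 1L || k > model$K) stop("topic index out of range: ", k)
  if (t < 1L || t > model$T) stop("slice index out of range: ", t)
  model$phi[[k]][, t]
}

#' Write / read fitted-model artifacts
#'
#' Plain-text artifacts under a directory: one CSV of natural parameters
#' per topic (`b_topic<k>.csv`, V rows x T columns, word column first), a
#' `gamma.csv` with the document-topic Dirichlet parameters, and a
#' `manifest.json` recording dimensions, hyperparameters, the objective
#' trace and the seed.
#'
#' @param fit result of [fit_dtm()].
#' @param dir output directory (created if needed).
#' @param cfg the [fit_config()] used (stored in the manifest).
#' @return `write_model` returns `dir` invisibly; `read_model` a
#'   `dtm_model`.
#' @export
write_model <- function(fit, dir, cfg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- fit$model
  for (k in seq_len(model$K)) {
    df <- data.frame(word = model$vocab, model$b[[k]],
                     check.names = FALSE)
    names(df) <- c("word", paste0("slice", seq_len(model$T)))
    utils::write.csv(df, file.path(dir, sprintf("b_topic%03d.csv", k)),
                     row.names = FALSE)
  }
  gamma <- as.data.frame(fit$posterior$gamma)
  names(gamma) <- paste0("topic", seq_len(model$K))
  gamma <- cbind(slice = fit$posterior$doc_slice, gamma)
  utils::write.csv(gamma, file.path(dir, "gamma.csv"), row.names = FALSE)
  manifest <- list(
    package = "biodtm",
    version = as.character(utils::packageVersion("biodtm")),
    K = model$K, V = model$V, T = model$T,
    alpha = model$alpha, sigma2 = model$sigma2, sigma0_2 = model$sigma0_2,
    iterations = fit$iterations, converged = fit$converged,
    objective_trace = fit$trace
  )
  if (!is.null(cfg)) {
    manifest$config <- unclass(cfg)
    manifest$seed <- cfg$seed
    manifest$config_hash <- fnv1a_hash(
      jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)
    )
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  K <- manifest$K
  b <- vector("list", K)
  vocab <- NULL
  for (k in seq_len(K)) {
    df <- utils::read.csv(file.path(dir, sprintf("b_topic%03d.csv", k)),
                          check.names = FALSE)
    vocab <- df$word
    b[[k]] <- as.matrix(df[, -1L, drop = FALSE])
    dimnames(b[[k]]) <- NULL
  }
  model <- structure(
    list(K = K, V = manifest$V, T = manifest$T, alpha = manifest$alpha,
         sigma2 = manifest$sigma2, sigma0_2 = manifest$sigma0_2,
         vocab = vocab, b = b),
    class = "dtm_model"
  )
  model_refresh_phi(model)
}
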