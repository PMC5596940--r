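#' Softmax of a numeric vector
#'
#' Numerically stable transformation from natural parameters to a
#' probability vector.
#'
#' @param x numeric vector.
#' @return probability vector of the same length summing to 1.
#' @export
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Total variation distance between two probability vectors
#'
#' @param p,q probability vectors of equal length.
#' @return half the L1 distance, in `[0, 1]`.
#' @export
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  sum(abs(p - q)) / 2
}

#' Optimal topic matching between two model parameterizations
#'
#' Solves the assignment problem between `K` reference topics and `K`
#' candidate topics under a caller-supplied cost matrix (typically mean
#' total-variation distance over slices), by exhaustive search over
#' permutations.  Exact for the small `K` used in recovery harnesses.
#'
#' @param cost `K x K` matrix, `cost[i, j]` = cost of matching reference
#'   topic `i` to candidate topic `j`.
#' @return list with `perm` (candidate index assigned to each reference
#'   topic) and `cost` (mean matched cost).
#' @export
match_topics <- function(cost) {
  K <- nrow(cost)
  stopifnot(is.matrix(cost), ncol(cost) == K, K <= 8L)
  perms <- permutations_of(K)
  costs <- vapply(
    perms,
    function(p) mean(cost[cbind(seq_len(K), p)]),
    numeric(1)
  )
  best <- which.min(costs)
  list(perm = perms[[best]], cost = costs[best])
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos)
    }
  }
  out
}

# FNV-1a 32-bit hash of a string, reported as 8 hex digits.  Used only to
# fingerprint configurations in output manifests (no crypto intent).
# Arithmetic is done in doubles with an explicit 16/16-bit split so the
# 32-bit modular product stays exact.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h1 <- floor(h / 65536)
    h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
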