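# Independent oracles used to cross-check package computations.

# Benjamini-Hochberg step-up, written out literally from the procedure:
# sort p ascending, q_i = p_i * m / i, enforce monotonicity from the
# largest rank down, cap at 1, restore input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Hypergeometric upper tail by direct log-space summation of the pmf.
oracle_hyper_tail <- function(N, K, n, k) {
  ks <- k:min(K, n)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# Brute-force betweenness: BFS shortest-path counting per source, then
# accumulate pair dependencies by explicit enumeration over all unordered
# pairs (s, t).
oracle_betweenness <- function(A) {
  n <- nrow(A)
  A <- (A > 0) * 1
  diag(A) <- 0
  dist_mat <- matrix(Inf, n, n)
  count_mat <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    cnt <- rep(0, n)
    dist[s] <- 0
    cnt[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] > 0)) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1) cnt[w] <- cnt[w] + cnt[v]
        }
      }
      frontier <- unique(nxt)
    }
    dist_mat[s, ] <- dist
    count_mat[s, ] <- cnt
  }
  # sigma_st(v): shortest s-t paths through v = sigma_sv * sigma_vt when
  # d(s,v) + d(v,t) == d(s,t)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v) next
        if (is.infinite(dist_mat[s, t])) next
        if (dist_mat[s, v] + dist_mat[v, t] == dist_mat[s, t]) {
          bc[v] <- bc[v] + count_mat[s, v] * count_mat[v, t] / count_mat[s, t]
        }
      }
    }
  }
  bc
}

# Random symmetric adjacency with unit self-loops (valid convolution input).
random_weighted_graph <- function(n, p_edge = 0.4, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p_edge)
  A <- A + t(A)
  diag(A) <- 1
  dimnames(A) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  A
}
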