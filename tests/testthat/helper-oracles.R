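# Independent oracles: textbook formulas and brute-force enumerations kept
# deliberately separate from the package's implementation paths.

# Two-pass covariance/variance Pearson correlation.
oracle_cor <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Two-sided p from the t distribution with n - 2 df.
oracle_cor_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

# Phi coefficient from the 2x2 contingency table of two binary vectors.
oracle_phi <- function(x, y) {
  n11 <- sum(x == 1 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  n00 <- sum(x == 0 & y == 0)
  (n11 * n00 - n10 * n01) /
    sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
}

# Newman-Girvan modularity evaluated directly from the adjacency matrix:
# Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) [c_i == c_j]
oracle_q <- function(graph, membership) {
  a <- as.matrix(igraph::as_adjacency_matrix(graph))
  m2 <- sum(a)  # 2m
  if (m2 == 0) return(0)
  k <- rowSums(a)
  same <- outer(membership, membership, "==")
  sum((a - outer(k, k) / m2) * same) / m2
}

# Freeman degree centralization by hand.
oracle_centralization <- function(graph) {
  d <- igraph::degree(graph)
  n <- length(d)
  sum(max(d) - d) / ((n - 1) * (n - 2))
}

# All set partitions of 1..n as membership vectors (restricted growth strings).
set_partitions <- function(n) {
  out <- list()
  recur <- function(prefix, k) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(k + 1L)) recur(c(prefix, b), max(k, b))
  }
  recur(integer(), 0L)
  out
}

# Exhaustive maximum-modularity partition (n <= 8).
oracle_best_partition <- function(graph) {
  n <- igraph::vcount(graph)
  stopifnot(n <= 8L)
  parts <- set_partitions(n)
  qs <- vapply(parts, function(p) oracle_q(graph, p), 0)
  best <- which.max(qs)
  list(membership = parts[[best]], q = qs[best])
}

# Independent G(n, m) sampler: uniform m-subset of the C(n, 2) possible
# edges.
oracle_gnm <- function(n, m) {
  pairs <- t(utils::combn(n, 2))
  idx <- sample.int(nrow(pairs), m)
  el <- data.frame(from = as.character(pairs[idx, 1]), to = as.character(pairs[idx, 2]))
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = data.frame(name = as.character(seq_len(n))))
}

# Mann-Whitney U by exhaustive pair counting (ties count 1/2).
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
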