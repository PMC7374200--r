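# Brute-force oracles, independent of the package's (igraph-backed) paths.
# All operate on a symmetric weighted adjacency matrix with zero diagonal.

# Floyd-Warshall hop distances (edges counted as 1 wherever weight > 0)
bf_hop_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Floyd-Warshall on explicit edge lengths (Inf where no edge)
bf_weighted_distances <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

bf_closeness <- function(adj) {
  d <- bf_hop_distances(adj)
  (nrow(adj) - 1) / rowSums(d)
}

# geodesic-counting betweenness, pair-normalized
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- bf_hop_distances(adj)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (dist in seq_len(max(d[s, ]))) {
      for (t in which(d[s, ] == dist)) {
        preds <- which(adj[, t] > 0 & d[s, ] == dist - 1)
        sigma[s, t] <- sum(sigma[s, preds])
      }
    }
  }
  bc <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (s == v || t == v || s == t) next
    if (d[s, v] + d[v, t] == d[s, t])
      bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
  }
  names(bc) <- rownames(adj)
  bc / ((n - 1) * (n - 2) / 2)
}

bf_kshell <- function(adj) {
  n <- nrow(adj)
  alive <- rep(TRUE, n)
  shell <- setNames(integer(n), rownames(adj))
  k <- 0L
  while (any(alive)) {
    k <- k + 1L
    repeat {
      deg <- rowSums(adj[, alive, drop = FALSE] > 0) * alive
      drop <- alive & deg <= k
      if (!any(drop)) break
      shell[drop] <- k
      alive[drop] <- FALSE
      if (!any(alive)) break
    }
  }
  shell
}

# sum over all length-k walks i -> j of the product of edge weights
bf_walk_weight <- function(adj, i, j, k) {
  if (k == 0L) return(as.numeric(i == j))
  total <- 0
  for (m in seq_len(nrow(adj))) {
    if (adj[i, m] > 0)
      total <- total + adj[i, m] * bf_walk_weight(adj, m, j, k - 1L)
  }
  total
}

# tie-aware Kendall tau-b by O(n^2) pair counting
bf_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
    if (a * b > 0) conc <- conc + 1 else if (a * b < 0) disc <- disc + 1
    if (a == 0) tx <- tx + 1
    if (b == 0) ty <- ty + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# mean weighted shortest-path distance over unordered pairs after setting
# every edge length to 2 except edges incident to v (length 1)
bf_reduced_avg_dist <- function(adj, v) {
  len <- matrix(Inf, nrow(adj), ncol(adj), dimnames = dimnames(adj))
  len[adj > 0] <- 2
  len[v, adj[v, ] > 0] <- 1
  len[adj[, v] > 0, v] <- 1
  d <- bf_weighted_distances(len)
  mean(d[upper.tri(d)])
}

expect_scores_equal <- function(sv, expected, tol = 1e-10) {
  expect_equal(as.numeric(sv[names(expected)]), as.numeric(expected),
               tolerance = tol)
}
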