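#' Network diameter in unweighted hops
#'
#' The maximum over node pairs of the shortest-path hop count. Edge weights
#' are co-occurrence counts, not lengths, so distance here is always hop
#' distance.
#'
#' @param net a connected `acupoint_network` with at least 2 nodes.
#' @return positive integer.
#' @export
graph_diameter <- function(net) {
  stop_if_disconnected(net, "graph diameter")
  if (length(net$nodes) < 2L) stop("diameter needs at least 2 nodes")
  as.integer(igraph::diameter(net$graph, weights = NA))
}

#' Walk-influence profile from adjacency-matrix powers
#'
#' For the weighted adjacency matrix A, the (i, m) entry of A^k accumulates
#' the edge-weight products over all length-k walks from i to m. The profile
#' collects, for each walk length k = 1..D (D the hop diameter):
#' \describe{
#'   \item{theta_node\[i, k\]}{`theta_i^k = sum_{m != i} A^k[i, m]`, node i's
#'     weighted influence at length k (at k = 1 this is the weighted degree)}
#'   \item{theta_total\[k\]}{`theta^k = 1/2 sum_{n != m} A^k[n, m]`, the
#'     network total, counting each unordered pair once}
#' }
#' Powers are taken by repeated matrix multiplication.
#'
#' @param net a connected `acupoint_network`.
#' @return an `influence_profile`: list with `D`, `theta_node` (N x D
#'   matrix, rows named by node), `theta_total` (length-D vector).
#' @export
influence_profile <- function(net) {
  stop_if_disconnected(net, "influence profile")
  a <- adn_adjacency(net)
  d <- graph_diameter(net)
  n <- nrow(a)
  theta_node <- matrix(0, n, d, dimnames = list(rownames(a), NULL))
  theta_total <- numeric(d)
  ak <- diag(n)
  for (k in seq_len(d)) {
    ak <- ak %*% a
    off <- rowSums(ak) - diag(ak)
    theta_node[, k] <- off
    theta_total[k] <- sum(off) / 2
  }
  structure(list(D = d, theta_node = theta_node, theta_total = theta_total),
            class = "influence_profile")
}

#' @export
print.influence_profile <- function(x, ...) {
  cat(sprintf("influence_profile: %d nodes, diameter D = %d\n",
              nrow(x$theta_node), x$D))
  cat("theta_total by walk length:", format(x$theta_total, digits = 4), "\n")
  invisible(x)
}

#' The Key_node influence index
#'
#' Scores each node by its share of total weighted walk influence, summed
#' over walk lengths 1..D:
#' `Key_node(v_i) = sum_{k=1}^{D} theta_i^k / theta^k`.
#' Because `sum_i theta_i^k = 2 theta^k` for every k, the scores always sum
#' to `2 D` on a connected network.
#'
#' @param net a connected `acupoint_network`.
#' @param percent if `TRUE`, multiply scores by 100 (the percentage reading
#'   used when tabulating results).
#' @return a `score_vector` named `"Key_node"`.
#' @export
key_node_score <- function(net, percent = FALSE) {
  prof <- influence_profile(net)
  if (any(prof$theta_total <= 0))
    stop("theta^k is zero for some walk length; degenerate network")
  shares <- sweep(prof$theta_node, 2, prof$theta_total, "/")
  s <- rowSums(shares)
  if (percent) s <- 100 * s
  score_vector(s[net$nodes], "Key_node")
}
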