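#' Construct a score vector
#'
#' A named numeric vector covering every node of the network it was computed
#' on, tagged with the method that produced it. Ties are preserved as equal
#' values; rank/tie-breaking is left to the mining stage.
#'
#' @param scores named numeric vector.
#' @param method method name string.
#' @return a `score_vector`.
#' @export
score_vector <- function(scores, method) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  structure(scores, method = method, class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("score_vector [%s], %d nodes\n", attr(x, "method"), length(x)))
  print(utils::head(sort(unclass(x), decreasing = TRUE), 10L))
  invisible(x)
}

#' @export
as.data.frame.score_vector <- function(x, ...) {
  data.frame(entity_id = names(x), method = attr(x, "method"),
             score = as.numeric(x), row.names = NULL)
}

#' Unweighted degree centrality
#' @param net an `acupoint_network`.
#' @return a `score_vector` of neighbor counts.
#' @export
degree_centrality <- function(net) {
  d <- igraph::degree(net$graph)
  score_vector(d[net$nodes], "degree")
}

#' Weighted degree (node strength)
#'
#' The sum of incident edge weights, i.e. `s_i = sum_j w_ij` — equal to the
#' length-1 entry of the influence profile and to the `s_i` numerator of the
#' weight-reduction benchmark.
#' @param net an `acupoint_network`.
#' @return a `score_vector`.
#' @export
weighted_degree <- function(net) {
  s <- igraph::strength(net$graph, weights = igraph::E(net$graph)$weight)
  score_vector(s[net$nodes], "weighted_degree")
}

#' Closeness centrality on hop distances
#'
#' `C_C(v_i) = (N - 1) / sum_j d_ij` with `d_ij` the unweighted
#' shortest-path hop count. Defined only for connected networks.
#' @param net an `acupoint_network`.
#' @return a `score_vector`.
#' @export
closeness_centrality <- function(net) {
  stop_if_disconnected(net, "closeness centrality")
  cc <- igraph::closeness(net$graph, weights = NA, normalized = TRUE)
  score_vector(cc[net$nodes], "CC")
}

#' Betweenness centrality on hop distances, pair-normalized
#' @param net an `acupoint_network`.
#' @return a `score_vector`.
#' @export
betweenness_centrality <- function(net) {
  bc <- igraph::betweenness(net$graph, weights = NA, normalized = TRUE)
  score_vector(bc[net$nodes], "BC")
}

#' Eigenvector centrality of the weighted adjacency matrix
#'
#' Principal eigenvector by power iteration on the weighted adjacency
#' matrix; L2-normalized, oriented nonnegative.
#'
#' @param net an `acupoint_network` (connected).
#' @param tol convergence tolerance on the L2 change per iteration.
#' @param max_iter iteration cap.
#' @return a `score_vector`.
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 10000L) {
  stop_if_disconnected(net, "eigenvector centrality")
  a <- adn_adjacency(net)
  n <- nrow(a)
  if (n == 1L) return(score_vector(setNames(1, rownames(a)), "EC"))
  # diagonal shift: leaves the principal eigenvector unchanged but prevents
  # the +/-lambda oscillation on (near-)bipartite graphs; scaled to the
  # matrix so the iteration stays weight-scale invariant
  shift <- max(rowSums(a)) / 2
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(a %*% x) + shift * x
    ny <- sqrt(sum(y^2))
    if (ny == 0) stop("power iteration hit the zero vector")
    y <- y / ny
    if (sqrt(sum((y - x)^2)) < tol) {
      if (sum(y) < 0) y <- -y
      return(score_vector(setNames(pmax(y, 0), rownames(a)), "EC"))
    }
    x <- y
  }
  stop(sprintf("eigenvector centrality did not converge in %d iterations", max_iter))
}

#' k-shell (k-core) decomposition index
#'
#' Classic unweighted iterative degree pruning; each node scores the shell
#' index at which it is removed. Edge weights are ignored.
#' @param net an `acupoint_network`.
#' @return a `score_vector` of integer shell indexes.
#' @export
k_shell <- function(net) {
  ks <- igraph::coreness(net$graph)
  score_vector(ks[net$nodes], "k-shell")
}

#' Clustered local degree centrality
#'
#' Combines the degrees of a node's neighbors with its own local clustering
#' coefficient. The default formula is
#' `CLD(i) = sum_{j in N(i)} k_j / (1 + c_i)`, with `k_j` the unweighted
#' degree of neighbor `j` and `c_i` the local clustering coefficient
#' (taken as 0 where undefined, i.e. degree < 2). The combination rule is
#' pluggable via `formula`.
#'
#' @param net an `acupoint_network`.
#' @param formula function of `(neighbor_degree_sum, clustering)` returning
#'   the score; the default implements the rule above.
#' @return a `score_vector`.
#' @export
cld_centrality <- function(net,
                           formula = function(nbr_deg_sum, clustering)
                             nbr_deg_sum / (1 + clustering)) {
  g <- net$graph
  deg <- igraph::degree(g)
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(cl) <- igraph::V(g)$name
  nbr_sum <- vapply(igraph::V(g)$name, function(v) {
    nb <- igraph::neighbors(g, v)
    sum(deg[nb$name])
  }, numeric(1))
  score_vector(formula(nbr_sum, cl[names(nbr_sum)])[net$nodes], "CLD")
}

#' All baseline centralities by name
#'
#' @param net an `acupoint_network`.
#' @param methods subset of `c("degree", "CC", "BC", "EC", "k-shell",
#'   "CLD", "Key_node")`.
#' @return named list of `score_vector`s.
#' @export
compute_centralities <- function(net,
                                 methods = c("degree", "CC", "BC", "EC",
                                             "k-shell", "CLD", "Key_node")) {
  known <- list(
    "degree"   = degree_centrality,
    "CC"       = closeness_centrality,
    "BC"       = betweenness_centrality,
    "EC"       = eigenvector_centrality,
    "k-shell"  = k_shell,
    "CLD"      = cld_centrality,
    "Key_node" = key_node_score
  )
  bad <- setdiff(methods, names(known))
  if (length(bad) > 0L)
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(names(known), collapse = ", "))
  setNames(lapply(methods, function(m) known[[m]](net)), methods)
}
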