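#' Ranking resolution
#'
#' Groups the scores into R distinct-value classes (after rounding to 10
#' significant digits, so floating-point noise does not inflate R) and
#' computes `f = 1 - sum_i N_i^2 / (R * n^2)`. A constant ranking (R = 1)
#' has f = 0; all-distinct scores approach 1 as n grows. The companion
#' `delta = 1 - f` is the form used when smaller-is-better tables are
#' reported.
#'
#' @param scores a `score_vector` (or named numeric) covering all `n` nodes.
#' @param n number of nodes; defaults to `length(scores)`.
#' @return list with `f`, `delta`, and `ranking` (a `ranking_result`:
#'   data.frame of score classes in descending score order with columns
#'   `class`, `score`, `size`, `members`).
#' @export
resolution <- function(scores, n = length(scores)) {
  if (n == 0L) stop("resolution undefined for n = 0")
  if (length(scores) != n)
    stop(sprintf("scores cover %d nodes but n = %d", length(scores), n))
  key <- signif(as.numeric(scores), 10)
  classes <- sort(unique(key), decreasing = TRUE)
  sizes <- vapply(classes, function(cl) sum(key == cl), integer(1))
  members <- vapply(classes, function(cl)
    paste(sort(names(scores)[key == cl]), collapse = ";"), character(1))
  r <- length(classes)
  f <- 1 - sum(sizes^2) / (r * n^2)
  ranking <- data.frame(class = seq_len(r), score = classes, size = sizes,
                        members = members, row.names = NULL)
  class(ranking) <- c("ranking_result", "data.frame")
  list(f = f, delta = 1 - f, ranking = ranking)
}

#' Cumulative distribution of ranking granularity
#'
#' Points for the CDF curve of a ranking: the cumulative fraction of nodes
#' absorbed by the first k score classes, classes ordered by descending
#' score. The slope from the origin to the final point (R, 1) summarizes
#' resolution: shallower means finer granularity.
#'
#' @param ranking a `ranking_result` from [resolution()].
#' @return data.frame with columns `class` and `cum_fraction`; the final
#'   row is `(R, 1)`.
#' @export
cdf_curve <- function(ranking) {
  n <- sum(ranking$size)
  data.frame(class = ranking$class,
             cum_fraction = cumsum(ranking$size) / n)
}

star_normalizer <- function(n) (n - 1) * (n + 2) / 4

#' Connectivity loss from deleting one node
#'
#' Deleting `target` loses, directly, its connections to every other node
#' (DLOS: sum of reciprocal original hop distances from the target), and,
#' indirectly, any surviving pair that the deletion disconnects (ILOS: sum
#' of reciprocal original distances over such pairs). `TLOS = DLOS + ILOS`
#' is normalized by the star-center maximum, `C = 4 TLOS / ((N-1)(N+2))`,
#' so the center of any star scores exactly 1.
#'
#' @param net a connected `acupoint_network`.
#' @param target a node id.
#' @return a `loss_report`: list with `target`, `dlos`, `ilos`, `tlos`, `c`.
#' @export
node_deletion_loss <- function(net, target) {
  if (!target %in% net$nodes) stop("unknown target node: ", target)
  set_deletion_loss(net, target)
}

#' Connectivity loss from deleting a node set
#'
#' All targets are removed simultaneously. DLOS sums 1/d (original hop
#' distances) over unordered pairs with at least one deleted endpoint, each
#' pair counted once; ILOS sums 1/d over surviving pairs disconnected after
#' the deletion. The single-node star normalizer is retained, so set losses
#' are comparable across sets on the same network.
#'
#' @param net a connected `acupoint_network`.
#' @param targets non-empty character vector of node ids, not all nodes.
#' @return a `loss_report`.
#' @export
set_deletion_loss <- function(net, targets) {
  stop_if_disconnected(net, "deletion loss")
  targets <- unique(targets)
  unknown <- setdiff(targets, net$nodes)
  if (length(unknown) > 0L)
    stop("unknown target node(s): ", paste(unknown, collapse = ", "))
  n <- length(net$nodes)
  if (length(targets) >= n) stop("cannot delete every node")
  d <- igraph::distances(net$graph, weights = NA)
  d <- d[net$nodes, net$nodes]
  is_del <- net$nodes %in% targets
  inv <- 1 / d
  diag(inv) <- 0
  # direct: unordered pairs touching >= 1 deleted endpoint
  del_block <- inv[is_del, is_del, drop = FALSE]
  cross_block <- inv[is_del, !is_del, drop = FALSE]
  dlos <- sum(del_block) / 2 + sum(cross_block)
  # indirect: surviving pairs disconnected post-deletion, at original distances
  survivors <- net$nodes[!is_del]
  g_del <- igraph::delete_vertices(net$graph, targets)
  memb <- igraph::components(g_del)$membership[survivors]
  same <- outer(memb, memb, "==")
  sub <- inv[survivors, survivors, drop = FALSE]
  ilos <- sum(sub[!same]) / 2
  tlos <- dlos + ilos
  structure(list(target = targets, dlos = dlos, ilos = ilos, tlos = tlos,
                 c = tlos / star_normalizer(n)),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("deletion loss for {%s}: DLOS = %.4f, ILOS = %.4f, TLOS = %.4f, C = %.4f\n",
              paste(x$target, collapse = ", "), x$dlos, x$ilos, x$tlos, x$c))
  invisible(x)
}

#' Weight-reduction benchmark score
#'
#' A position-based reference importance: for each node v, every edge is
#' given length 2 except the edges incident to v, which get length 1; `l_v`
#' is the mean weighted shortest-path length over all unordered node pairs
#' in that modified network. A well-placed node shrinks the network's
#' average distance more. The score is `W(v) = s_v / l_v` with `s_v` the
#' weighted degree in the original network.
#'
#' @param net a connected `acupoint_network`.
#' @return a `score_vector` named `"benchmark"`.
#' @export
weight_reduction_benchmark <- function(net) {
  stop_if_disconnected(net, "weight-reduction benchmark")
  g <- net$graph
  n <- length(net$nodes)
  npairs <- n * (n - 1) / 2
  s <- weighted_degree(net)
  ends <- igraph::ends(g, igraph::E(g))
  w <- vapply(net$nodes, function(v) {
    len <- ifelse(ends[, 1] == v | ends[, 2] == v, 1, 2)
    dm <- igraph::distances(g, weights = len)
    l_v <- sum(dm[upper.tri(dm)]) / npairs
    as.numeric(s[v]) / l_v
  }, numeric(1))
  score_vector(w, "benchmark")
}

#' Tie-aware Kendall rank correlation (tau-b)
#'
#' @param a,b `score_vector`s (or named numerics) over the same node set.
#' @return tau in \[-1, 1\].
#' @export
kendall_tau <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)) ||
      !setequal(names(a), names(b)) || length(a) != length(b))
    stop("kendall_tau needs two score vectors over the same node set")
  ids <- sort(names(a))
  cor(as.numeric(a[ids]), as.numeric(b[ids]), method = "kendall")
}

#' Full method comparison: resolution, network loss, benchmark accuracy
#'
#' For each method, computes the full-network score vector, its resolution
#' complement `Delta = 1 - f`, the normalized network loss `C(U)` of its
#' per-community key set, and the Kendall tau between its full-network
#' ranking and the weight-reduction benchmark.
#'
#' @param net a connected `acupoint_network`.
#' @param methods method names (see [compute_centralities()]).
#' @param per_community key-set size per community (default 2).
#' @param per_community_candidates candidate-stage size for the proposed
#'   method (default 4).
#' @return list with `table` (data.frame: method, delta, c_u, tau),
#'   `scores` (list of `score_vector`s), `key_sets` (list of
#'   `key_node_set`s), and `benchmark` (the benchmark `score_vector`).
#' @export
evaluate_all <- function(net, methods = c("degree", "CC", "BC", "EC",
                                          "k-shell", "CLD", "Key_node"),
                         per_community = 2L, per_community_candidates = 4L) {
  scores <- compute_centralities(net, methods)
  key_sets <- comparison_key_sets(net, methods, per_community,
                                  per_community_candidates)
  bench <- weight_reduction_benchmark(net)
  rows <- lapply(methods, function(m) {
    data.frame(method = m,
               delta = resolution(scores[[m]])$delta,
               c_u = set_deletion_loss(net, key_sets[[m]]$entity_id)$c,
               tau = kendall_tau(scores[[m]], bench))
  })
  list(table = do.call(rbind, rows), scores = scores, key_sets = key_sets,
       benchmark = bench)
}
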