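#' Deterministic within-community ranking
#'
#' Orders nodes by score (descending), breaking ties by weighted degree
#' (descending) and then lexicographically by entity id. The rule is total,
#' so identical inputs always produce identical orders.
#' @noRd
rank_nodes <- function(ids, scores, wdeg) {
  ids[order(-scores[ids], -wdeg[ids], ids)]
}

#' Stage 1: community-constrained candidate selection
#'
#' For each community, picks the `per_community` nodes with highest
#' closeness centrality; a community with fewer nodes contributes all of
#' them. With the defaults and 15 communities the candidate set has at most
#' 60 members.
#'
#' @param net a connected `acupoint_network` with every node
#'   community-labeled.
#' @param per_community candidates per community (default 4).
#' @return a `candidate_set`: data.frame with columns `community`, `rank`,
#'   `entity_id`, `score` (closeness), ordered by community then rank.
#' @export
select_candidates <- function(net, per_community = 4L) {
  stop_if_disconnected(net, "candidate selection")
  cc <- closeness_centrality(net)
  wd <- weighted_degree(net)
  by_comm <- split(net$nodes, net$communities)
  empty <- vapply(by_comm, length, integer(1)) == 0L
  if (any(empty)) {
    warning("empty community(ies) skipped: ",
            paste(names(by_comm)[empty], collapse = ", "))
    by_comm <- by_comm[!empty]
  }
  rows <- lapply(sort(names(by_comm)), function(cm) {
    ids <- rank_nodes(by_comm[[cm]], cc, wd)
    ids <- ids[seq_len(min(per_community, length(ids)))]
    data.frame(community = cm, rank = seq_along(ids), entity_id = ids,
               score = as.numeric(cc[ids]), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Stage 2: key-node selection from the candidate set
#'
#' Within each community, re-ranks the candidates by the `Key_node`
#' influence index and keeps the top `per_community`. A candidate need not
#' have top closeness to win: the influence index weighs edge weights,
#' which closeness ignores.
#'
#' @param net the `acupoint_network` the candidates came from.
#' @param candidates a `candidate_set` from [select_candidates()].
#' @param per_community key nodes per community (default 2).
#' @return a `key_node_set`: data.frame with columns `community`, `rank`,
#'   `entity_id`, `score` (Key_node).
#' @export
select_key_nodes <- function(net, candidates, per_community = 2L) {
  kn <- key_node_score(net)
  wd <- weighted_degree(net)
  rows <- lapply(sort(unique(candidates$community)), function(cm) {
    ids <- candidates$entity_id[candidates$community == cm]
    ids <- rank_nodes(ids, kn, wd)
    ids <- ids[seq_len(min(per_community, length(ids)))]
    data.frame(community = cm, rank = seq_along(ids), entity_id = ids,
               score = as.numeric(kn[ids]), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("key_node_set", "data.frame")
  out
}

#' Per-community key sets for baseline methods
#'
#' For a fair comparison, each baseline ranks nodes directly within every
#' community by its own score (no closeness pre-filter) and keeps the top
#' `per_community`. The proposed method (`"Key_node"`) always goes through
#' the candidate stage first, exactly as the mining pipeline orders the
#' steps.
#'
#' @param net a connected `acupoint_network`.
#' @param methods character vector of method names (see
#'   [compute_centralities()]).
#' @param per_community nodes kept per community (default 2).
#' @param per_community_candidates candidate-stage size used for the
#'   proposed method (default 4).
#' @return named list of `key_node_set` data.frames, one per method.
#' @export
comparison_key_sets <- function(net, methods = c("degree", "CC", "BC", "EC",
                                                 "k-shell", "CLD", "Key_node"),
                                per_community = 2L,
                                per_community_candidates = 4L) {
  scores <- compute_centralities(net, methods)
  wd <- weighted_degree(net)
  by_comm <- split(net$nodes, net$communities)
  by_comm <- by_comm[vapply(by_comm, length, integer(1)) > 0L]
  out <- lapply(methods, function(m) {
    if (m == "Key_node") {
      cand <- select_candidates(net, per_community = per_community_candidates)
      return(select_key_nodes(net, cand, per_community = per_community))
    }
    sv <- scores[[m]]
    rows <- lapply(sort(names(by_comm)), function(cm) {
      ids <- rank_nodes(by_comm[[cm]], sv, wd)
      ids <- ids[seq_len(min(per_community, length(ids)))]
      data.frame(community = cm, rank = seq_along(ids), entity_id = ids,
                 score = as.numeric(sv[ids]), row.names = NULL)
    })
    res <- do.call(rbind, rows)
    class(res) <- c("key_node_set", "data.frame")
    res
  })
  setNames(out, methods)
}

#' One-hop coverage of a seed set
#'
#' The fraction of all nodes that are a seed or adjacent to at least one
#' seed — the "cooperation range" of a set of activated nodes.
#'
#' @param net an `acupoint_network`.
#' @param seeds character vector of node ids.
#' @return fraction in (0, 1].
#' @export
coverage_1hop <- function(net, seeds) {
  unknown <- setdiff(seeds, net$nodes)
  if (length(unknown) > 0L)
    stop("unknown seed id(s): ", paste(unknown, collapse = ", "))
  covered <- unique(c(seeds, unlist(lapply(seeds, function(v)
    igraph::neighbors(net$graph, v)$name))))
  length(covered) / length(net$nodes)
}
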