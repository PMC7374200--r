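#' Construct a prescription table
#'
#' A prescription table maps each condition (disease) to the set of entities
#' (acupoints) prescribed for it. Duplicate (condition, entity) rows are
#' collapsed with a warning: an entity either belongs to a prescription or it
#' does not, and a pair co-occurring in one condition contributes exactly 1
#' to its edge weight regardless of row multiplicity.
#'
#' @param condition_id character vector, one entry per row.
#' @param entity_id character vector, same length as `condition_id`.
#' @param max_size maximum entities allowed per condition (default 10,
#'   the "top ten prescription points per disease" convention of the source
#'   data model). Use `Inf` to disable.
#' @return A `prescription_table`: data.frame with columns `condition_id`,
#'   `entity_id`, one row per (condition, entity) membership.
#' @export
prescription_table <- function(condition_id, entity_id, max_size = 10) {
  stopifnot(length(condition_id) == length(entity_id))
  if (length(condition_id) == 0L) stop("prescription table is empty")
  tab <- data.frame(condition_id = as.character(condition_id),
                    entity_id = as.character(entity_id),
                    stringsAsFactors = FALSE)
  if (anyNA(tab) || any(tab$condition_id == "") || any(tab$entity_id == ""))
    stop("prescription table contains missing or empty ids")
  dup <- duplicated(tab)
  if (any(dup)) {
    warning(sprintf("%d duplicated (condition, entity) row(s) removed", sum(dup)))
    tab <- tab[!dup, , drop = FALSE]
  }
  sizes <- table(tab$condition_id)
  if (any(sizes > max_size))
    stop(sprintf("condition(s) exceed maximum prescription size %s: %s",
                 max_size, paste(names(sizes)[sizes > max_size], collapse = ", ")))
  rownames(tab) <- NULL
  class(tab) <- c("prescription_table", "data.frame")
  tab
}

#' Split a prescription table into per-condition entity sets
#' @param prescriptions a `prescription_table`.
#' @return named list of character vectors (entity ids per condition).
#' @export
prescription_sets <- function(prescriptions) {
  split(prescriptions$entity_id, prescriptions$condition_id)
}

#' Build the weighted co-occurrence network
#'
#' Every prescription induces a clique among its entities; the weight of an
#' edge is the number of conditions whose prescriptions contain both
#' endpoints, so `0 <= w_ij <= (number of conditions)`. Nodes are ordered
#' lexicographically by entity id so adjacency matrices are reproducible.
#' Entities present in the community map but absent from every prescription
#' are excluded; entities with no community assignment are an error.
#'
#' @param prescriptions a `prescription_table` (or a 2-column data.frame
#'   with `condition_id`, `entity_id`).
#' @param communities named character vector mapping entity id to community
#'   id; must cover every entity appearing in `prescriptions`.
#' @param exclude optional character vector of entity ids to drop before
#'   building (curation exclusions).
#' @return An `acupoint_network`: a list with elements
#'   \describe{
#'     \item{graph}{an igraph object with edge attribute `weight` and vertex
#'       attribute `community`}
#'     \item{nodes}{character vector of entity ids, lexicographic}
#'     \item{communities}{named character vector, node -> community}
#'     \item{n_conditions}{number of conditions used}
#'   }
#' @export
build_adn <- function(prescriptions, communities, exclude = NULL) {
  if (!inherits(prescriptions, "prescription_table"))
    prescriptions <- prescription_table(prescriptions$condition_id,
                                        prescriptions$entity_id,
                                        max_size = Inf)
  if (!is.null(exclude))
    prescriptions <- prescriptions[!prescriptions$entity_id %in% exclude, ,
                                   drop = FALSE]
  if (nrow(prescriptions) == 0L) stop("prescription table is empty")
  sets <- split(prescriptions$entity_id, prescriptions$condition_id)
  nodes <- sort(unique(prescriptions$entity_id))
  missing <- setdiff(nodes, names(communities))
  if (length(missing) > 0L)
    stop("entities without community assignment: ",
         paste(missing, collapse = ", "))
  n <- length(nodes)
  w <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (s in sets) {
    if (length(s) < 2L) next
    idx <- match(sort(s), nodes)
    prs <- combn(idx, 2L)
    for (p in seq_len(ncol(prs))) {
      i <- prs[1L, p]; j <- prs[2L, p]
      w[i, j] <- w[i, j] + 1
      w[j, i] <- w[j, i] + 1
    }
  }
  comm <- setNames(as.character(communities[nodes]), nodes)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$community <- comm[igraph::V(g)$name]
  net <- structure(list(graph = g, nodes = nodes, communities = comm,
                        n_conditions = length(sets)),
                   class = "acupoint_network")
  if (!connected_check(net)$connected)
    message("note: the built network is disconnected; ",
            "diameter/closeness/Key_node will refuse it")
  net
}

#' Assemble an acupoint network directly from an edge list
#'
#' @param edges data.frame with columns `source`, `target`, `weight`
#'   (positive numbers).
#' @param communities named character vector, entity id -> community id,
#'   covering every endpoint.
#' @return an `acupoint_network`; `n_conditions` is `NA` (unknown origin).
#' @export
adn_from_edgelist <- function(edges, communities) {
  stopifnot(all(c("source", "target", "weight") %in% names(edges)))
  if (nrow(edges) == 0L) stop("edge list is empty")
  if (any(edges$weight <= 0)) stop("edges must have positive weight")
  if (any(edges$source == edges$target)) stop("self-loops are not allowed")
  key <- paste(pmin(edges$source, edges$target),
               pmax(edges$source, edges$target))
  if (anyDuplicated(key)) {
    dups <- key[duplicated(key)]
    conf <- vapply(unique(dups), function(k) {
      length(unique(edges$weight[key == k])) > 1L
    }, logical(1))
    if (any(conf))
      stop("duplicate edges with conflicting weights: ",
           paste(unique(dups)[conf], collapse = ", "))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  nodes <- sort(unique(c(edges$source, edges$target)))
  missing <- setdiff(nodes, names(communities))
  if (length(missing) > 0L)
    stop("entities without community assignment: ",
         paste(missing, collapse = ", "))
  n <- length(nodes)
  w <- matrix(0, n, n, dimnames = list(nodes, nodes))
  i <- match(edges$source, nodes); j <- match(edges$target, nodes)
  w[cbind(i, j)] <- edges$weight
  w[cbind(j, i)] <- edges$weight
  comm <- setNames(as.character(communities[nodes]), nodes)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$community <- comm[igraph::V(g)$name]
  structure(list(graph = g, nodes = nodes, communities = comm,
                 n_conditions = NA_integer_),
            class = "acupoint_network")
}

#' Weighted adjacency matrix of a network
#' @param net an `acupoint_network`.
#' @return symmetric numeric matrix with zero diagonal, nodes in
#'   lexicographic order.
#' @export
adn_adjacency <- function(net) {
  a <- igraph::as_adjacency_matrix(net$graph, attr = "weight", sparse = FALSE)
  a[net$nodes, net$nodes, drop = FALSE]
}

#' Connectivity check with component partition
#' @param net an `acupoint_network`.
#' @return list with `connected` (logical) and `components` (list of
#'   character vectors of node ids).
#' @export
connected_check <- function(net) {
  cc <- igraph::components(net$graph)
  comps <- split(names(cc$membership), cc$membership)
  names(comps) <- NULL
  list(connected = cc$no == 1L, components = comps)
}

stop_if_disconnected <- function(net, what) {
  cc <- connected_check(net)
  if (!cc$connected) {
    sizes <- vapply(cc$components, length, integer(1))
    stop(sprintf("%s requires a connected network; found %d components (sizes %s)",
                 what, length(sizes), paste(sizes, collapse = ", ")))
  }
  invisible(net)
}

#' @export
print.acupoint_network <- function(x, ...) {
  cat(sprintf("acupoint_network: %d nodes, %d edges, %d communities\n",
              length(x$nodes), igraph::ecount(x$graph),
              length(unique(x$communities))))
  if (!is.na(x$n_conditions))
    cat(sprintf("built from %d conditions\n", x$n_conditions))
  invisible(x)
}
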