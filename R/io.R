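#' Read a prescription table from CSV/TSV
#'
#' Expects a header row and two columns, `condition_id` and `entity_id`,
#' UTF-8 encoded. Duplicated rows are deduplicated with a warning (see
#' [prescription_table()]).
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.tsv` -> tab, otherwise comma) unless `sep` is given.
#' @param sep optional field separator.
#' @param max_size maximum prescription size accepted (default 10).
#' @return a `prescription_table`.
#' @export
read_prescriptions <- function(path, sep = NULL, max_size = 10) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character", encoding = "UTF-8")
  need <- c("condition_id", "entity_id")
  if (!all(need %in% names(raw)))
    stop("prescription file must have columns condition_id, entity_id; found: ",
         paste(names(raw), collapse = ", "))
  bad <- which(is.na(raw$condition_id) | raw$condition_id == "" |
               is.na(raw$entity_id) | raw$entity_id == "")
  if (length(bad) > 0L)
    stop("malformed prescription rows (missing ids) at line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  prescription_table(raw$condition_id, raw$entity_id, max_size = max_size)
}

#' Write a prescription table to CSV
#' @param prescriptions a `prescription_table`.
#' @param path output path.
#' @export
write_prescriptions <- function(prescriptions, path) {
  write.csv(as.data.frame(prescriptions)[, c("condition_id", "entity_id")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a community map from CSV
#'
#' @param path CSV with header and columns `entity_id`, `community_id`.
#' @return named character vector, entity id -> community id.
#' @export
read_communities <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  encoding = "UTF-8")
  need <- c("entity_id", "community_id")
  if (!all(need %in% names(raw)))
    stop("community file must have columns entity_id, community_id; found: ",
         paste(names(raw), collapse = ", "))
  bad <- which(is.na(raw$entity_id) | raw$entity_id == "" |
               is.na(raw$community_id) | raw$community_id == "")
  if (length(bad) > 0L)
    stop("malformed community rows at line(s): ", paste(bad + 1L, collapse = ", "))
  dup <- duplicated(raw$entity_id)
  if (any(dup)) {
    conflicting <- vapply(unique(raw$entity_id[dup]), function(e)
      length(unique(raw$community_id[raw$entity_id == e])) > 1L, logical(1))
    if (any(conflicting))
      stop("entities assigned to multiple communities: ",
           paste(unique(raw$entity_id[dup])[conflicting], collapse = ", "))
    raw <- raw[!dup, , drop = FALSE]
  }
  setNames(raw$community_id, raw$entity_id)
}

#' Write a community map to CSV
#' @param communities named character vector, entity id -> community id.
#' @param path output path.
#' @export
write_communities <- function(communities, path) {
  write.csv(data.frame(entity_id = names(communities),
                       community_id = unname(communities)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a network as weighted edge list + node attributes
#'
#' Writes two CSV files: an edge list (`source`, `target`, `weight`) at
#' `path` and a node-attribute table (`entity_id`, `community_id`) at
#' `nodes_path`. `read_network()` on the pair reproduces the network
#' exactly, including isolated-free weights and community labels.
#'
#' @param net an `acupoint_network`.
#' @param path edge-list CSV path.
#' @param nodes_path node-attribute CSV path (default: `path` with
#'   `_nodes.csv` suffix).
#' @export
write_network <- function(net, path,
                          nodes_path = sub("\\.csv$", "_nodes.csv", path)) {
  el <- igraph::as_data_frame(net$graph, what = "edges")
  el <- el[order(el$from, el$to), c("from", "to", "weight")]
  names(el) <- c("source", "target", "weight")
  write.csv(el, path, row.names = FALSE, quote = FALSE)
  write_communities(net$communities, nodes_path)
  invisible(c(path, nodes_path))
}

#' Read a network from weighted edge list + node attributes
#'
#' @param path edge-list CSV (`source`, `target`, `weight`; weights must be
#'   positive — zero-weight rows are rejected).
#' @param nodes_path node-attribute CSV (`entity_id`, `community_id`).
#' @return an `acupoint_network`.
#' @export
read_network <- function(path, nodes_path = sub("\\.csv$", "_nodes.csv", path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  el <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("source", "target", "weight")
  if (!all(need %in% names(el)))
    stop("edge list must have columns source, target, weight; found: ",
         paste(names(el), collapse = ", "))
  el$weight <- suppressWarnings(as.numeric(el$weight))
  bad <- which(is.na(el$weight) | el$weight <= 0)
  if (length(bad) > 0L)
    stop("edges must have positive numeric weight; bad line(s): ",
         paste(bad + 1L, collapse = ", "))
  communities <- read_communities(nodes_path)
  unknown <- setdiff(unique(c(el$source, el$target)), names(communities))
  if (length(unknown) > 0L)
    stop("edge endpoints missing from node-attribute table: ",
         paste(unknown, collapse = ", "))
  adn_from_edgelist(el, communities)
}

#' Export a network to GraphML
#'
#' Edge weights go to the `weight` edge attribute and community labels to
#' the `community` node attribute.
#'
#' @param net an `acupoint_network`.
#' @param path output `.graphml` path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' Import a network from GraphML
#' @param path a `.graphml` file with `weight` edge and `community` node
#'   attributes.
#' @return an `acupoint_network`.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  if (is.null(igraph::E(g)$weight)) stop("GraphML file lacks a weight edge attribute")
  if (is.null(igraph::V(g)$community)) stop("GraphML file lacks a community node attribute")
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[1:2] <- c("source", "target")
  comm <- setNames(igraph::V(g)$community, igraph::V(g)$name)
  adn_from_edgelist(el[, c("source", "target", "weight")], comm)
}

#' Export score vectors as long-format CSV
#' @param scores a `score_vector` or list of them.
#' @param path output CSV path; columns `entity_id`, `method`, `score`.
#' @export
write_scores <- function(scores, path) {
  if (inherits(scores, "score_vector")) scores <- list(scores)
  rows <- do.call(rbind, lapply(scores, function(s)
    data.frame(entity_id = names(s), method = attr(s, "method"),
               score = as.numeric(s))))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
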