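#' Run the full build / score / mine / evaluate pipeline
#'
#' Executes the end-to-end analysis: build the co-occurrence network from a
#' prescription table, score every node with all requested methods, select
#' candidates and key nodes under the community constraint, and evaluate
#' all methods. Artifacts are written to `output_dir`:
#' \describe{
#'   \item{network.csv / network_nodes.csv}{weighted edge list + node
#'     attributes}
#'   \item{network.graphml}{GraphML export}
#'   \item{scores.csv}{long-format per-node scores for every method}
#'   \item{candidates.csv, key_nodes.csv}{the two mining stages}
#'   \item{comparison_key_sets.csv}{per-method community key sets}
#'   \item{evaluation.csv}{method, delta, c_u, tau}
#'   \item{cdf_curves.csv}{CDF points per method}
#'   \item{manifest.txt}{inputs, parameters, counts, versions}
#' }
#'
#' @param prescriptions a `prescription_table` or a path to a prescriptions
#'   CSV.
#' @param communities a named character vector or a path to a community CSV.
#' @param output_dir directory for artifacts (created if absent).
#' @param per_community_candidates candidate-stage size (default 4).
#' @param per_community_keys key-stage size (default 2).
#' @param methods methods to score and compare.
#' @param exclude optional entity ids to drop before building.
#' @return (invisibly) list with `network`, `candidates`, `key_nodes`,
#'   `evaluation`.
#' @export
run_pipeline <- function(prescriptions, communities, output_dir,
                         per_community_candidates = 4L,
                         per_community_keys = 2L,
                         methods = c("degree", "CC", "BC", "EC", "k-shell",
                                     "CLD", "Key_node"),
                         exclude = NULL) {
  is_path <- function(x) is.character(x) && length(x) == 1L && is.null(names(x))
  input_desc <- c(
    prescriptions = if (is_path(prescriptions)) prescriptions else "<in-memory>",
    communities = if (is_path(communities)) communities else "<in-memory>")
  if (is_path(prescriptions)) prescriptions <- read_prescriptions(prescriptions)
  if (is_path(communities)) communities <- read_communities(communities)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  message("[build] constructing network")
  net <- build_adn(prescriptions, communities, exclude = exclude)
  message(sprintf("[build] N = %d nodes, M = %d edges, %d communities present",
                  length(net$nodes), igraph::ecount(net$graph),
                  length(unique(net$communities))))
  stop_if_disconnected(net, "the pipeline")
  write_network(net, file.path(output_dir, "network.csv"))
  write_graphml(net, file.path(output_dir, "network.graphml"))
  message(sprintf("[build] diameter D = %d", graph_diameter(net)))

  message("[score] computing centralities: ", paste(methods, collapse = ", "))
  scores <- compute_centralities(net, methods)
  write_scores(scores, file.path(output_dir, "scores.csv"))

  message("[mine] selecting candidates and key nodes")
  cand <- select_candidates(net, per_community = per_community_candidates)
  keys <- select_key_nodes(net, cand, per_community = per_community_keys)
  message(sprintf("[mine] %d candidates, %d key nodes across %d communities",
                  nrow(cand), nrow(keys), length(unique(cand$community))))
  write.csv(cand, file.path(output_dir, "candidates.csv"), row.names = FALSE)
  write.csv(keys, file.path(output_dir, "key_nodes.csv"), row.names = FALSE)

  message("[eval] resolution, network loss, benchmark accuracy")
  ev <- evaluate_all(net, methods, per_community = per_community_keys,
                     per_community_candidates = per_community_candidates)
  write.csv(ev$table, file.path(output_dir, "evaluation.csv"),
            row.names = FALSE)
  comp <- do.call(rbind, lapply(names(ev$key_sets), function(m)
    cbind(method = m, ev$key_sets[[m]])))
  write.csv(comp, file.path(output_dir, "comparison_key_sets.csv"),
            row.names = FALSE)
  cdfs <- do.call(rbind, lapply(names(ev$scores), function(m)
    cbind(method = m, cdf_curve(resolution(ev$scores[[m]])$ranking))))
  write.csv(cdfs, file.path(output_dir, "cdf_curves.csv"), row.names = FALSE)

  manifest <- c(
    sprintf("acunet %s / R %s / igraph %s",
            as.character(utils::packageVersion("acunet")),
            paste(R.version$major, R.version$minor, sep = "."),
            as.character(utils::packageVersion("igraph"))),
    sprintf("input prescriptions: %s", input_desc[["prescriptions"]]),
    sprintf("input communities: %s", input_desc[["communities"]]),
    sprintf("per_community_candidates: %d", per_community_candidates),
    sprintf("per_community_keys: %d", per_community_keys),
    sprintf("methods: %s", paste(methods, collapse = ",")),
    sprintf("excluded entities: %s",
            if (is.null(exclude)) "none" else paste(exclude, collapse = ",")),
    sprintf("nodes: %d  edges: %d  conditions: %s  diameter: %d",
            length(net$nodes), igraph::ecount(net$graph),
            as.character(net$n_conditions), graph_diameter(net)),
    sprintf("candidates: %d  key nodes: %d", nrow(cand), nrow(keys)))
  writeLines(manifest, file.path(output_dir, "manifest.txt"))

  invisible(list(network = net, candidates = cand, key_nodes = keys,
                 evaluation = ev))
}
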