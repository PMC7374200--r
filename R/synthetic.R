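#' Configuration for the synthetic prescription generator
#'
#' Defaults emulate the data shape the mining method assumes: 50 common
#' conditions, 135 entities spread over 15 communities, at most 10 entities
#' per prescription, and Zipf-skewed entity popularity so a few hub
#' entities recur across many prescriptions (the heavy-tailed, scale-free-
#' like weight structure of real prescription corpora).
#'
#' @param n_conditions number of conditions (default 50).
#' @param n_entities number of entities (default 135).
#' @param n_communities number of communities (default 15).
#' @param prescription_size entities per condition (default 10).
#' @param popularity_exponent Zipf exponent for entity popularity
#'   (default 1; 0 means uniform).
#' @param community_size_profile `"auto"` (two small communities of 2
#'   entities, echoing sparsely represented meridians, the rest balanced),
#'   `"balanced"` (all nearly equal), or an integer vector of sizes summing
#'   to `n_entities`.
#' @param seed integer RNG seed; the generator is deterministic given the
#'   full config.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_conditions = 50L, n_entities = 135L,
                             n_communities = 15L, prescription_size = 10L,
                             popularity_exponent = 1,
                             community_size_profile = "auto",
                             seed = 1L) {
  if (prescription_size > n_entities)
    stop("prescription_size exceeds n_entities")
  if (n_communities > n_entities)
    stop("n_communities exceeds n_entities")
  structure(list(n_conditions = as.integer(n_conditions),
                 n_entities = as.integer(n_entities),
                 n_communities = as.integer(n_communities),
                 prescription_size = as.integer(prescription_size),
                 popularity_exponent = popularity_exponent,
                 community_size_profile = community_size_profile,
                 seed = as.integer(seed)),
            class = "generator_config")
}

community_sizes <- function(config) {
  k <- config$n_communities; n <- config$n_entities
  prof <- config$community_size_profile
  if (is.numeric(prof)) {
    if (length(prof) != k || sum(prof) != n || any(prof < 1))
      stop("community_size_profile must be ", k, " positive sizes summing to ", n)
    return(as.integer(prof))
  }
  if (identical(prof, "balanced") || k < 3L || n < 2L * 2L + (k - 2L)) {
    base <- rep(n %/% k, k)
    base[seq_len(n %% k)] <- base[seq_len(n %% k)] + 1L
    return(base)
  }
  # auto: two sparse communities of 2, rest balanced
  rest <- n - 4L
  base <- rep(rest %/% (k - 2L), k - 2L)
  base[seq_len(rest %% (k - 2L))] <- base[seq_len(rest %% (k - 2L))] + 1L
  c(base, 2L, 2L)
}

#' Generate a synthetic prescription table and community map
#'
#' Entities are partitioned into communities per the config's size profile.
#' Entity popularity follows a Zipf law over a random permutation drawn
#' from the seed (so popularity is independent of community labels); each
#' condition samples `prescription_size` distinct entities without
#' replacement with probability proportional to `rank^-exponent`. If the
#' induced co-occurrence network is disconnected, the table is resampled
#' (bounded retries) and, failing that, a single bridging condition joining
#' one entity per component is appended, with a message.
#'
#' @param config a [generator_config()].
#' @return list with `prescriptions` (a `prescription_table`),
#'   `communities` (named character vector over all configured entities),
#'   and `network` (the induced connected `acupoint_network`).
#' @export
generate_prescriptions <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  entities <- sprintf("A%03d", seq_len(config$n_entities))
  comm_ids <- sprintf("M%02d", seq_len(config$n_communities))
  sizes <- community_sizes(config)
  communities <- setNames(rep(comm_ids, times = sizes), entities)
  pop_rank <- sample(config$n_entities)  # permutation: rank of each entity
  prob <- pop_rank^(-config$popularity_exponent)
  draw_table <- function() {
    rows <- lapply(seq_len(config$n_conditions), function(i) {
      picked <- sample(entities, config$prescription_size, prob = prob)
      data.frame(condition_id = sprintf("D%02d", i),
                 entity_id = sort(picked))
    })
    do.call(rbind, rows)
  }
  max_retry <- 20L
  for (attempt in seq_len(max_retry)) {
    tab <- draw_table()
    net <- build_net_quietly(tab, communities)
    if (connected_check(net)$connected) break
    if (attempt == max_retry) {
      comps <- connected_check(net)$components
      reps <- vapply(comps, `[`, character(1), 1L)
      reps <- reps[seq_len(min(length(reps), config$prescription_size))]
      message("bridging condition added to connect ", length(comps),
              " components")
      tab <- rbind(tab, data.frame(condition_id = "Dbridge",
                                   entity_id = sort(reps)))
      net <- build_net_quietly(tab, communities)
    }
  }
  prescriptions <- prescription_table(tab$condition_id, tab$entity_id,
                                      max_size = config$prescription_size)
  list(prescriptions = prescriptions, communities = communities,
       network = net)
}

build_net_quietly <- function(tab, communities) {
  suppressMessages(build_adn(prescription_table(tab$condition_id,
                                                tab$entity_id,
                                                max_size = Inf),
                             communities))
}

make_fixture <- function(edges, communities) {
  adn_from_edgelist(edges, communities)
}

#' Small hand-analyzed fixture networks
#'
#' Toy networks whose centralities and losses are known in closed form or
#' by hand computation, used as oracles throughout the test suite:
#' \describe{
#'   \item{star4}{star with center `c` and 3 leaves, unit weights; the
#'     center attains the maximum normalized deletion loss C = 1.}
#'   \item{path3}{path a-b-c, unit weights; Key_node = (1.5, 1.0, 1.5).}
#'   \item{k4}{complete graph on 4 nodes, unit weights; diameter 1.}
#'   \item{tri_pendant}{triangle a-b-c plus pendant d on c; shells (2,2,2,1).}
#'   \item{gprime}{4-node weighted graph (w(v1,v2)=2, w(v1,v3)=1,
#'     w(v2,v3)=3, w(v2,v4)=1) with hop diameter 2.}
#'   \item{twoclique}{the network induced by two prescriptions
#'     d1 = \{a,b,c\}, d2 = \{b,c,d\}: 5 edges, w(b,c) = 2.}
#' }
#'
#' @return named list of `acupoint_network` objects.
#' @export
fixture_graphs <- function() {
  one <- function(ids) setNames(rep("C1", length(ids)), ids)
  star4 <- make_fixture(
    data.frame(source = "c", target = c("l1", "l2", "l3"), weight = 1),
    one(c("c", "l1", "l2", "l3")))
  path3 <- make_fixture(
    data.frame(source = c("a", "b"), target = c("b", "c"), weight = 1),
    one(c("a", "b", "c")))
  k4 <- fixture_complete(4L)
  tri_pendant <- make_fixture(
    data.frame(source = c("a", "a", "b", "c"),
               target = c("b", "c", "c", "d"), weight = 1),
    one(letters[1:4]))
  gprime <- make_fixture(
    data.frame(source = c("v1", "v1", "v2", "v2"),
               target = c("v2", "v3", "v3", "v4"),
               weight = c(2, 1, 3, 1)),
    one(c("v1", "v2", "v3", "v4")))
  twoclique <- suppressMessages(build_adn(
    prescription_table(rep(c("d1", "d2"), each = 3),
                       c("a", "b", "c", "b", "c", "d")),
    setNames(rep("C1", 4), c("a", "b", "c", "d"))))
  list(star4 = star4, path3 = path3, k4 = k4, tri_pendant = tri_pendant,
       gprime = gprime, twoclique = twoclique)
}

#' Parametric star fixture
#' @param n total nodes (center plus n-1 leaves), n >= 3.
#' @return an `acupoint_network`.
#' @export
fixture_star <- function(n) {
  leaves <- sprintf("l%02d", seq_len(n - 1L))
  make_fixture(data.frame(source = "c", target = leaves, weight = 1),
               setNames(rep("C1", n), c("c", leaves)))
}

#' Parametric path fixture
#' @param n nodes, n >= 2.
#' @return an `acupoint_network`.
#' @export
fixture_path <- function(n) {
  ids <- sprintf("p%02d", seq_len(n))
  make_fixture(data.frame(source = ids[-n], target = ids[-1], weight = 1),
               setNames(rep("C1", n), ids))
}

#' Parametric complete-graph fixture
#' @param n nodes, n >= 2.
#' @return an `acupoint_network`.
#' @export
fixture_complete <- function(n) {
  ids <- sprintf("k%02d", seq_len(n))
  prs <- t(combn(ids, 2L))
  make_fixture(data.frame(source = prs[, 1], target = prs[, 2], weight = 1),
               setNames(rep("C1", n), ids))
}

#' Random connected weighted network for property tests
#'
#' Erdos-Renyi draw with integer weights, resampled until connected.
#' @param n nodes; `p` edge probability; `max_weight` integer weight cap;
#'   `n_communities` community labels assigned round-robin.
#' @return an `acupoint_network`.
#' @export
random_connected_network <- function(n, p = 0.3, max_weight = 5L,
                                     n_communities = 1L) {
  ids <- sprintf("r%03d", seq_len(n))
  comm <- setNames(rep(sprintf("M%02d", seq_len(n_communities)),
                       length.out = n), ids)
  repeat {
    prs <- t(combn(ids, 2L))
    keep <- stats::runif(nrow(prs)) < p
    if (sum(keep) == 0L) next
    edges <- data.frame(source = prs[keep, 1], target = prs[keep, 2],
                        weight = sample.int(max_weight, sum(keep),
                                            replace = TRUE))
    if (length(unique(c(edges$source, edges$target))) < n) next
    net <- adn_from_edgelist(edges, comm)
    if (connected_check(net)$connected) return(net)
  }
}
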