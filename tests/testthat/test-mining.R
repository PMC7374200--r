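# toy with a clear community structure: two K4 cliques joined by a bridge x
bridge_toy <- function() {
  cl <- function(prefix) {
    ids <- paste0(prefix, 1:4)
    prs <- t(combn(ids, 2))
    data.frame(source = prs[, 1], target = prs[, 2], weight = 1)
  }
  edges <- rbind(cl("a"), cl("b"),
                 data.frame(source = c("a1", "b1"), target = c("x", "x"),
                            weight = 1))
  comm <- setNames(rep("C1", 9), c(paste0("a", 1:4), paste0("b", 1:4), "x"))
  adn_from_edgelist(edges, comm)
}

test_that("candidate selection takes the most central nodes per community", {
  p5 <- fixture_path(5)
  cand <- select_candidates(p5, per_community = 4)
  # closeness order on P5: center, the two inner, then a lexicographic tie-break
  expect_equal(cand$entity_id, c("p03", "p02", "p04", "p01"))
  expect_equal(cand$rank, 1:4)
  expect_equal(cand$score[1], 4 / 6)
})

test_that("a community smaller than the quota contributes all its nodes", {
  set.seed(50)
  net <- random_connected_network(12, p = 0.5, n_communities = 1)
  # relabel: two nodes into a tiny community, rest elsewhere
  net$communities[] <- "M1"
  net$communities[c("r001", "r002")] <- "M2"
  igraph::V(net$graph)$community <- net$communities[igraph::V(net$graph)$name]
  cand <- select_candidates(net, per_community = 4)
  expect_equal(sum(cand$community == "M2"), 2)
  expect_setequal(cand$entity_id[cand$community == "M2"], c("r001", "r002"))
  keys <- select_key_nodes(net, cand)
  expect_equal(sum(keys$community == "M2"), 2)
})

test_that("key-node stage re-ranks candidates by influence, not closeness", {
  set.seed(51)
  for (i in 1:5) {
    net <- random_connected_network(sample(10:20, 1), p = 0.35,
                                    max_weight = 8, n_communities = 3)
    cand <- select_candidates(net, per_community = 4)
    keys <- select_key_nodes(net, cand, per_community = 2)
    kn <- key_node_score(net)
    wd <- weighted_degree(net)
    expect_true(all(keys$entity_id %in% cand$entity_id))
    for (cm in unique(keys$community)) {
      ids <- cand$entity_id[cand$community == cm]
      expected <- ids[order(-kn[ids], -wd[ids], ids)]
      expected <- expected[seq_len(min(2, length(expected)))]
      expect_identical(keys$entity_id[keys$community == cm], expected)
    }
  }
})

test_that("heavy-edged low-closeness candidates can win the key stage", {
  # c2 and c3 share one heavy edge; h1 and h2 have the best closeness but
  # only unit weights, so the influence stage overturns the closeness order
  edges <- data.frame(
    source = c("h1", "h1", "h1", "h2", "h2", "c3"),
    target = c("h2", "c1", "c2", "c1", "c3", "c2"),
    weight = c(1, 1, 1, 1, 1, 30))
  comm <- c(h1 = "A", h2 = "A", c1 = "A", c2 = "A", c3 = "A")
  net <- adn_from_edgelist(edges, comm)
  cand <- select_candidates(net, per_community = 4)
  keys <- select_key_nodes(net, cand, per_community = 2)
  expect_identical(cand$entity_id[1:2], c("h1", "h2"))
  expect_setequal(keys$entity_id, c("c2", "c3"))
  expect_true(all(match(keys$entity_id, cand$entity_id) > 2))
})

test_that("baseline comparison sets rank directly per community and can differ", {
  net <- bridge_toy()
  sets <- comparison_key_sets(net, methods = c("degree", "BC", "Key_node"),
                              per_community = 2)
  expect_setequal(sets$degree$entity_id, c("a1", "b1"))  # degree 4 hubs
  expect_setequal(sets$BC$entity_id, c("x", "a1"))       # bridge carries paths
  expect_false(setequal(sets$degree$entity_id, sets$BC$entity_id))
  # proposed method equals the two-stage pipeline output
  cand <- select_candidates(net, per_community = 4)
  expect_identical(sets$Key_node, select_key_nodes(net, cand))
  expect_error(comparison_key_sets(net, methods = "nope"), "unknown method")
})

test_that("complete-graph symmetry is broken deterministically and reproducibly", {
  k6 <- fixture_complete(6)
  s1 <- comparison_key_sets(k6, methods = c("degree", "CC", "Key_node"))
  s2 <- comparison_key_sets(k6, methods = c("degree", "CC", "Key_node"))
  expect_identical(s1, s2)
  for (m in names(s1))
    expect_identical(s1[[m]]$entity_id, c("k01", "k02"))  # lexicographic ties
})

test_that("key sets scale with communities and respect per-community caps", {
  set.seed(52)
  net3 <- random_connected_network(18, p = 0.4, n_communities = 3)
  net4 <- random_connected_network(24, p = 0.4, n_communities = 4)
  k3 <- select_key_nodes(net3, select_candidates(net3))
  k4 <- select_key_nodes(net4, select_candidates(net4))
  expect_equal(nrow(k3), 6)
  expect_equal(nrow(k4), 8)
  expect_true(all(table(k3$community) <= 2))
  cand <- select_candidates(net3, per_community = 4)
  expect_true(all(table(cand$community) <= 4))
})

test_that("one-hop coverage counts seeds and their neighbors", {
  fx <- fixture_graphs()
  expect_equal(coverage_1hop(fx$star4, "c"), 1)
  p4 <- fixture_path(4)
  expect_equal(coverage_1hop(p4, "p01"), 2 / 4)
  expect_equal(coverage_1hop(p4, p4$nodes), 1)
  expect_error(coverage_1hop(p4, "zz"), "unknown seed")
})
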