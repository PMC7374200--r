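fx <- fixture_graphs()

test_that("resolution matches hand-computed class structure", {
  const <- score_vector(setNames(rep(3.7, 20), sprintf("n%02d", 1:20)), "x")
  expect_identical(resolution(const)$f, 0)

  distinct <- score_vector(setNames(c(4, 3, 2, 1), letters[1:4]), "x")
  expect_equal(resolution(distinct)$f, 1 - 4 / (4 * 16))

  paired <- score_vector(setNames(c(2, 2, 1, 1), letters[1:4]), "x")
  r <- resolution(paired)
  expect_equal(r$f, 1 - 8 / (2 * 16))
  expect_equal(r$ranking$size, c(2, 2))
  expect_equal(r$delta, 1 - r$f)
  expect_error(resolution(score_vector(setNames(numeric(), character()), "x")),
               "n = 0")
})

test_that("resolution is bounded, maximal iff distinct, monotone-invariant", {
  set.seed(60)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    x <- setNames(sample(1:6, n, replace = TRUE), sprintf("n%02d", 1:n))
    f <- resolution(score_vector(x, "x"))$f
    expect_gte(f, 0)
    expect_lte(f, 1 - 1 / n^2)
    fd <- resolution(score_vector(x + seq_len(n) * 1e3, "x"))$f
    expect_equal(fd, 1 - 1 / n^2)  # all distinct attains the bound
    ft <- resolution(score_vector(exp(x / 2), "x"))$f
    expect_equal(ft, f)  # strictly monotone transform preserves classes
  }
})

test_that("CDF curve accumulates class sizes in descending score order", {
  one <- resolution(score_vector(setNames(rep(1, 3), c("a", "b", "c")), "x"))
  expect_equal(cdf_curve(one$ranking),
               data.frame(class = 1L, cum_fraction = 1))
  mixed <- resolution(score_vector(setNames(c(9, 5, 1, 1), letters[1:4]), "x"))
  expect_equal(cdf_curve(mixed$ranking)$cum_fraction, c(0.25, 0.5, 1.0))
  dist <- resolution(score_vector(setNames(4:1, letters[1:4]), "x"))
  cv <- cdf_curve(dist$ranking)
  expect_equal(nrow(cv), 4)
  expect_equal(cv$cum_fraction[4], 1)
})

test_that("single-node deletion loss matches hand computations", {
  center <- node_deletion_loss(fx$star4, "c")
  expect_equal(center$dlos, 3)
  expect_equal(center$ilos, 1.5)
  expect_equal(center$tlos, 4.5)
  expect_equal(center$c, 1)

  leaf <- node_deletion_loss(fx$star4, "l1")
  expect_equal(leaf$dlos, 2)
  expect_equal(leaf$ilos, 0)
  expect_equal(leaf$c, 8 / 18)
  expect_error(node_deletion_loss(fx$star4, "zz"), "unknown target")
})

test_that("the star center attains C = 1 exactly for every size", {
  for (n in c(3, 5, 12, 27, 50))
    expect_equal(node_deletion_loss(fixture_star(n), "c")$c, 1)
})

test_that("leaves never cause indirect loss; TLOS always splits into parts", {
  set.seed(61)
  for (i in 1:8) {
    net <- random_connected_network(sample(5:15, 1), p = 0.35)
    deg <- degree_centrality(net)
    for (v in sample(net$nodes, 3)) {
      rep <- node_deletion_loss(net, v)
      expect_equal(rep$tlos, rep$dlos + rep$ilos)
      if (deg[v] == 1) expect_equal(rep$ilos, 0)
      g_del <- igraph::delete_vertices(net$graph, v)
      if (igraph::is_connected(g_del)) expect_equal(rep$ilos, 0)
    }
  }
})

test_that("set deletion: singleton consistency, star leaves, articulation pair in P5", {
  set.seed(62)
  net <- random_connected_network(10, p = 0.4)
  v <- sample(net$nodes, 1)
  expect_equal(set_deletion_loss(net, v)[c("dlos", "ilos", "tlos", "c")],
               node_deletion_loss(net, v)[c("dlos", "ilos", "tlos", "c")])

  s5 <- fixture_star(5)
  two_leaves <- set_deletion_loss(s5, c("l01", "l02"))
  # pairs touching the leaves: 2x(center at 1, two other leaves at 1/2 each)
  # plus the deleted-deleted pair at 1/2
  expect_equal(two_leaves$dlos, 2 * (1 + 1 / 2 + 1 / 2) + 1 / 2)
  expect_equal(two_leaves$ilos, 0)

  p5 <- fixture_path(5)
  cut <- set_deletion_loss(p5, c("p02", "p04"))
  expect_equal(cut$dlos, 1 + 1 + 1 / 3 + 1 / 3 + 1 + 1 + 1 / 2)
  expect_equal(cut$ilos, 1 / 2 + 1 / 4 + 1 / 2)
  expect_error(set_deletion_loss(p5, p5$nodes), "every node")
})

test_that("weight-reduction benchmark matches hand values and the APSP oracle", {
  wb <- weight_reduction_benchmark(fx$path3)
  expect_equal(as.numeric(wb["b"]), 1.5)
  k2 <- adn_from_edgelist(data.frame(source = "a", target = "b", weight = 1),
                          c(a = "C1", b = "C1"))
  expect_true(all(weight_reduction_benchmark(k2) == 1))
  ws <- weight_reduction_benchmark(fx$star4)
  expect_true(all(ws["c"] > ws[c("l1", "l2", "l3")]))

  set.seed(63)
  for (i in 1:6) {
    net <- random_connected_network(sample(4:8, 1), p = 0.5, max_weight = 4)
    a <- adn_adjacency(net)
    s <- weighted_degree(net)
    w <- weight_reduction_benchmark(net)
    for (v in net$nodes)
      expect_equal(as.numeric(w[v]),
                   as.numeric(s[v]) / bf_reduced_avg_dist(a, v),
                   tolerance = 1e-12)
  }
})

test_that("Kendall tau: identities, one discordant pair, symmetry, brute-force match", {
  ids <- sprintf("n%02d", 1:8)
  x <- score_vector(setNames(rnorm(8), ids), "x")
  expect_equal(kendall_tau(x, x), 1)
  neg <- score_vector(setNames(-as.numeric(x), ids), "y")
  expect_equal(kendall_tau(x, neg), -1)

  a4 <- score_vector(setNames(c(4, 3, 2, 1), letters[1:4]), "a")
  b4 <- score_vector(setNames(c(4, 3, 1, 2), letters[1:4]), "b")
  expect_equal(kendall_tau(a4, b4), (5 - 1) / 6)

  set.seed(64)
  for (i in 1:10) {
    n <- sample(5:25, 1)
    ids <- sprintf("n%02d", 1:n)
    u <- score_vector(setNames(sample(1:5, n, TRUE), ids), "u")
    v <- score_vector(setNames(sample(1:5, n, TRUE), ids), "v")
    expect_equal(kendall_tau(u, v), bf_kendall(as.numeric(u[ids]),
                                               as.numeric(v[ids])),
                 tolerance = 1e-12)
    expect_equal(kendall_tau(u, v), kendall_tau(v, u))
  }
  expect_error(kendall_tau(a4, x), "same node set")
})

test_that("evaluate_all yields finite metrics per method and consistent tau", {
  set.seed(65)
  sim <- generate_prescriptions(generator_config(n_conditions = 20L,
                                                 n_entities = 40L,
                                                 n_communities = 5L,
                                                 prescription_size = 6L,
                                                 seed = 66L))
  ev <- evaluate_all(sim$network)
  expect_equal(nrow(ev$table), 7)
  expect_true(all(is.finite(ev$table$delta)))
  expect_true(all(is.finite(ev$table$c_u)))
  expect_true(all(ev$table$tau >= -1 & ev$table$tau <= 1))
  # tau for the proposed method uses the full-network Key_node scores
  expect_equal(ev$table$tau[ev$table$method == "Key_node"],
               kendall_tau(key_node_score(sim$network), ev$benchmark))
  # integer-valued degree ties more than the influence index
  expect_gte(ev$table$delta[ev$table$method == "degree"],
             ev$table$delta[ev$table$method == "Key_node"])
})
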