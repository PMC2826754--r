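test_that("edge-disjoint path counts follow Menger on hand-built graphs", {
  path3 <- make_net(c("s", "a"), c("a", "t"), c(0.9, 0.8))
  ps <- max_edge_disjoint_paths(path3, "s", "t")
  expect_equal(ps$d, 1L)
  expect_identical(ps$paths[[1L]], c("s", "a", "t"))

  k4e <- t(combn(c("s", "a", "b", "t"), 2))
  k4 <- make_net(k4e[, 1], k4e[, 2], rep(0.7, 6))
  expect_equal(max_edge_disjoint_paths(k4, "s", "t")$d, 3L)

  two_src <- make_net(c("s1", "s2"), c("t", "t"), c(0.5, 0.5))
  ps2 <- max_edge_disjoint_paths(two_src, c("s1", "s2"), "t")
  expect_equal(ps2$d, 2L)
  # artificial super-source edges never appear: paths start at a source
  expect_setequal(vapply(ps2$paths, `[`, "", 1L), c("s1", "s2"))
  expect_equal(ps2$lengths, c(1L, 1L))

  expect_error(max_edge_disjoint_paths(path3, c("s", "t"), "t"), "sink")
  iso <- make_net("s", "a", 0.5, isolated = "z")
  expect_equal(max_edge_disjoint_paths(iso, "s", "z")$d, 0L)
})

test_that("path failure probability is one minus the reliability product", {
  net <- make_net(c("a", "b", "c", "d"), c("b", "c", "d", "e"),
                  c(0.6, 0.6, 1.0, 0.5))
  expect_equal(path_failure_probability(c("a", "b", "c"), net), 0.64)
  expect_equal(path_failure_probability(c("c", "d"), net), 0)
  half <- make_net(c("a", "b", "c"), c("b", "c", "d"), rep(0.5, 3))
  expect_equal(path_failure_probability(c("a", "b", "c", "d"), half), 0.875)
  expect_error(path_failure_probability(c("a", "e"), net), "no such edge")
})

test_that("the product-form bound composes path failures", {
  net <- chain_net()
  pset <- max_edge_disjoint_paths(net, "s", "t")
  expect_equal(reliability_lower_bound(pset), 0.36)
  empty <- max_edge_disjoint_paths(make_net("s", "a", 0.5, isolated = "z"),
                                   "s", "z")
  expect_equal(reliability_lower_bound(empty), 0)
  dia <- make_net(c("s", "a", "s", "b"), c("a", "t", "b", "t"),
                  c(0.6, 1, 0.6, 1))  # two disjoint paths, P = 0.4 each
  expect_equal(reliability_lower_bound(max_edge_disjoint_paths(dia, "s", "t")),
               0.84)
})

test_that("netflow_score reproduces the worked chain and diamond bounds", {
  # a candidate two hops behind the query through a single route: 0.6*0.6
  frag <- make_net(c("p2", "p3", "p2"), c("p3", "p4", "p1"),
                   c(0.6, 0.6, 0.6))
  expect_equal(netflow_score(frag, "p2", "p4")$bound, 0.36)
  expect_equal(netflow_score(frag, "p2", "p1")$bound, 0.6)
  # node-disjoint diamond: bound equals exact reliability
  expect_equal(netflow_score(diamond_net(), "s", "t")$bound, 1 - 0.75^2)
})

test_that("exact_reliability matches closed forms and the independent oracle", {
  expect_equal(exact_reliability(chain_net(), "s", "t"), 0.36)
  expect_equal(exact_reliability(make_net("s", "t", 1), "s", "t"), 1.0)
  expect_equal(exact_reliability(diamond_net(), "s", "t"), 0.4375)
  for (seed in 1:12) {
    net <- random_net(5, 7, seed)
    nodes <- network_nodes(net)
    q <- nodes[1:2]; sink <- nodes[4]
    expect_equal(exact_reliability(net, q, sink), oracle_exact(net, q, sink),
                 tolerance = 1e-12)
  }
  big <- generate_network(n_nodes = 40, attach_edges = 2, n_complexes = 0,
                          seed = 1)$network
  expect_error(exact_reliability(big, "p01", "p02"), "mcs_reliability")
})

test_that("rank_candidates orders by bound with deterministic tie-break", {
  star <- make_net(c("c", "c"), c("x", "y"), c(0.9, 0.3))
  rk <- rank_candidates(star, "c")
  expect_identical(rk$sink, c("x", "y"))
  expect_equal(rk$bound, c(0.9, 0.3))

  iso <- make_net("a", "b", 0.5, isolated = c("z1", "z3", "z2"))
  rk2 <- rank_candidates(iso, "a")
  expect_equal(rk2$bound[rk2$sink != "b"], rep(0, 3))
  expect_identical(rk2$sink[rk2$bound == 0], c("z1", "z2", "z3"))

  gen <- generate_network(n_nodes = 20, attach_edges = 2, n_complexes = 1,
                          complex_size_range = c(3, 3), seed = 3)
  q <- gen$complexes[[1]]$members[-1]
  rk3 <- rank_candidates(gen$network, q)
  for (i in seq_len(nrow(rk3)))
    expect_equal(rk3$bound[i], netflow_score(gen$network, q, rk3$sink[i])$bound)
})

test_that("the bound is sound and tight in the disjoint regime", {
  n_tight <- 0L
  for (seed in 1:60) {
    net <- random_net(sample(4:7, 1), sample(4:11, 1), seed)
    nodes <- network_nodes(net)
    q <- nodes[1]; sink <- nodes[3]
    b <- netflow_score(net, q, sink)$bound
    ex <- exact_reliability(net, q, sink)
    expect_lte(b, ex + 1e-12)
    if (all_simple_paths_disjoint(net, q, sink)) {
      n_tight <- n_tight + 1L
      expect_equal(b, ex, tolerance = 1e-12)
    }
  }
  expect_gt(n_tight, 5L)  # the tightness branch must actually exercise
})

test_that("appending a disjoint path with P < 1 strictly increases the bound", {
  # compare the diamond bound against its single-path truncation
  dia <- diamond_net()
  pset <- max_edge_disjoint_paths(dia, "s", "t")
  expect_equal(pset$d, 2L)
  full <- reliability_lower_bound(pset)
  trunc <- pset
  trunc$paths <- trunc$paths[1]; trunc$failure <- trunc$failure[1]
  trunc$lengths <- trunc$lengths[1]; trunc$d <- 1L
  expect_gt(full, reliability_lower_bound(trunc))
})

test_that("netflow bounds ignore intermediate node degree", {
  net <- hub_contrast_net()
  expect_equal(netflow_score(net, "q", "u")$bound,
               netflow_score(net, "q", "v")$bound)
})
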