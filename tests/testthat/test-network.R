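test_that("BA growth adds exactly m edges per new node", {
  net <- ba_network(100, m = 5, m0 = 5, seed = 1)
  expect_equal(nrow(net$edges), 5 * 95)
  expect_equal(sum(net$degree), 2 * nrow(net$edges))

  tree <- ba_network(10, m = 1, m0 = 1, seed = 7)
  expect_equal(nrow(tree$edges), 9)
  # 9 edges on 10 nodes with no isolated node => a connected tree
  g <- igraph::graph_from_edgelist(tree$edges + 1L, directed = FALSE)
  expect_true(igraph::is_connected(g))
})

test_that("BA generator rejects invalid parameters by name", {
  expect_error(ba_network(5, m = 6, m0 = 5, seed = 0), "m <= m0")
  expect_error(ba_network(5, m = 5, m0 = 5, seed = 0), "m0 < n_nodes")
  expect_error(ba_network(10, m = 0, seed = 0), "m must be >= 1")
})

test_that("BA generation is deterministic in the seed", {
  a <- ba_network(200, m = 3, seed = 42)
  b <- ba_network(200, m = 3, seed = 42)
  expect_identical(a$edges, b$edges)
  c <- ba_network(200, m = 3, seed = 43)
  expect_false(identical(a$edges, c$edges))
})

test_that("networks are simple with a consistent degree sequence", {
  for (net in list(ba_network(50, 2, seed = 1), triangle_net(),
                   random_net(20, 0.4, seed = 9))) {
    expect_true(all(net$edges[, 1] < net$edges[, 2])) # no self-loops, canonical
    expect_false(any(duplicated(net$edges)))
    expect_equal(sum(net$degree), 2 * nrow(net$edges))
    recount <- tabulate(c(net$edges[, 1], net$edges[, 2]) + 1L, net$n_nodes)
    expect_equal(net$degree, as.integer(recount))
  }
})

test_that("mean degree approaches 2m for BA networks and is exact on small graphs", {
  net <- ba_network(5000, m = 5, seed = 11)
  expect_lt(abs(mean_degree(net) - 10) / 10, 0.01)
  expect_equal(mean_degree(triangle_net()), 2)
  expect_equal(mean_degree(isolated_net(1)), 0)
})

test_that("annealed adjacency follows k_i k_j / (2 m N)", {
  net <- ba_network(5000, m = 5, seed = 1)
  i <- which(net$degree == 5)[1] - 1L
  j <- which(net$degree == 5)[2] - 1L
  expect_equal(expected_adjacency(net, i, j), 25 / 50000)
  # symmetry, vectorized over random pairs
  set.seed(3)
  a <- sample(net$n_nodes, 50) - 1L
  b <- (a + sample(net$n_nodes - 1, 50)) %% net$n_nodes
  expect_equal(expected_adjacency(net, a, b), expected_adjacency(net, b, a))
  # isolated node has probability 0 under the formula
  net2 <- ba_network(20, m = 2, m0 = 5, seed = 2)
  if (any(net2$degree == 0)) {
    iso <- which(net2$degree == 0)[1] - 1L
    other <- which(net2$degree > 0)[1] - 1L
    expect_equal(expected_adjacency(net2, iso, other), 0)
  }
  # row sums are consistent with the degree normalization
  i <- 7L
  js <- setdiff(seq_len(net$n_nodes) - 1L, i)
  expect_equal(sum(expected_adjacency(net, rep(i, length(js)), js)),
               net$degree[i + 1] * (sum(net$degree) - net$degree[i + 1]) /
                 (2 * 5 * net$n_nodes))
  expect_error(expected_adjacency(net, 3, 3), "i != j")
  expect_error(expected_adjacency(triangle_net(), 0, 1), "missing metadata")
})

test_that("degree tail exponent is estimated for scale-free graphs and omitted for degenerate ones", {
  alphas <- vapply(1:20, function(s)
    degree_statistics(ba_network(5000, m = 5, seed = s))$tail_exponent,
    numeric(1))
  expect_true(all(is.finite(alphas)))
  expect_gt(mean(alphas), 2)
  expect_lt(mean(alphas), 3.5)

  stats <- degree_statistics(ba_network(5000, m = 5, seed = 1))
  expect_gt(stats$max_degree, stats$mean_degree)

  ring <- ring_net(200)
  expect_true(is.na(degree_statistics(ring, k_min = 2)$tail_exponent))
  small <- ba_network(50, m = 2, seed = 1)
  expect_true(is.na(degree_statistics(small)$tail_exponent))
})

test_that("edge lists round-trip, dedupe and reject malformed input", {
  net <- ba_network(30, m = 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".edges")
  write_edge_list(net, path)
  back <- read_edge_list(path)
  expect_identical(back$edges, net$edges)
  expect_identical(back$n_nodes, net$n_nodes)

  f <- withr::local_tempfile()
  writeLines(c("0 1", "1 2"), f)
  expect_equal(read_edge_list(f)$n_nodes, 3)
  writeLines(c("# comment", "0 1", "1 0"), f)
  expect_equal(nrow(read_edge_list(f)$edges), 1)
  writeLines("2 2", f)
  expect_error(read_edge_list(f), "self-loop")
  writeLines(c("0 1", "1 two"), f)
  expect_error(read_edge_list(f), "line 2")
})

test_that("GraphML round-trips nodes and edges", {
  net <- ba_network(25, m = 2, seed = 8)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, path)
  back <- read_graphml(path)
  expect_identical(back$edges, net$edges)
  expect_identical(back$n_nodes, net$n_nodes)
})
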