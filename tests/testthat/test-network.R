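test_that("loading collapses duplicate edges, drops self-loops, upper-cases ids", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "a\tb", "B\tC", "A\tB"), f)
  net <- load_network(f)
  expect_equal(sort(network_nodes(net)), c("A", "B", "C"))
  expect_equal(nrow(network_edges(net)), 2L)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("X\tX", "X\tY"), f2)
  expect_message(net2 <- load_network(f2), "self-loop")
  expect_equal(net2$dropped_self_loops, 1L)
  expect_equal(nrow(network_edges(net2)), 1L)
})

test_that("malformed and empty edge files are rejected with line context", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "oops"), f)
  expect_error(load_network(f), "line 2")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# only a comment", f2)
  expect_error(load_network(f2), "empty")
  expect_error(load_network(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("SIF input ignores the relation column", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tpp\tB", "B\tpp\tC"), f)
  net <- load_network(f)
  expect_equal(sort(network_nodes(net)), c("A", "B", "C"))
  expect_equal(unname(shortest_path_lengths(net, "A", "C")[1, 1]), 2)
})

test_that("generator round-trips through write and load unchanged", {
  net <- generate_network(n_nodes = 200, n_edges = 600, rng_seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f)
  net2 <- load_network(f)
  expect_equal(sort(network_nodes(net2)), sort(network_nodes(net)))
  expect_equal(network_edges(net2), network_edges(net))
  # idempotent: a second round trip is identical
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_network(net2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("distances match an independent BFS and flag unreachable pairs", {
  # path graph
  net <- interaction_network(cbind(c("A", "B"), c("B", "C")))
  expect_equal(unname(shortest_path_lengths(net, "A", "C")[1, 1]), 2)
  # two disconnected edges
  net2 <- interaction_network(cbind(c("A", "C"), c("B", "D")))
  expect_equal(unname(shortest_path_lengths(net2, "A", "D")[1, 1]), Inf)
  expect_error(shortest_path_lengths(net2, "A", "ZZ"), "ZZ")
  # random graph vs hand-rolled BFS
  g <- random_edge_graph(30, 0.1, seed = 1)
  used <- unique(as.vector(g$edges))
  net3 <- interaction_network(g$edges)
  d <- shortest_path_lengths(net3, used, used)
  for (s in used[1:10]) {
    expect_equal(d[s, used], oracle_bfs_dist(g$edges, g$nodes, s)[used])
  }
  # metric properties on the same graph
  expect_equal(d, t(d))
  finite <- is.finite(d)
  for (i in seq_len(10)) {
    trip <- d[used[1], ] <= d[used[1], used[i]] + d[used[i], ]
    expect_true(all(trip[finite[used[1], ] & finite[used[i], ]]))
  }
})

test_that("path profiles count all tied shortest paths through a node", {
  leaves <- paste0("L", 1:6)
  star <- interaction_network(cbind("C", leaves))
  pp <- path_profile(star, "C", leaves)
  expect_equal(pp$seed_pairs_covered, 15)
  expect_equal(pp$paths_through, 15)
  leaf <- path_profile(star, "L1", leaves)
  expect_equal(leaf$seed_pairs_covered, 0)
  expect_equal(leaf$paths_through, 0)
  expect_error(path_profile(star, "C", "L1"), "insufficient seeds")
})

test_that("grid-graph profiles match exhaustive path enumeration", {
  # 4x4 grid, seeds at the corners
  id <- function(i, j) sprintf("V%d%d", i, j)
  edges <- NULL
  for (i in 1:4) {
    for (j in 1:4) {
      if (i < 4) edges <- rbind(edges, c(id(i, j), id(i + 1, j)))
      if (j < 4) edges <- rbind(edges, c(id(i, j), id(i, j + 1)))
    }
  }
  net <- interaction_network(edges)
  corners <- c(id(1, 1), id(1, 4), id(4, 1), id(4, 4))
  oracle <- oracle_path_profile(net$graph, corners)
  for (i in 2:3) {
    for (j in 2:3) {
      pp <- path_profile(net, id(i, j), corners)
      expect_equal(pp$paths_through, unname(oracle$paths_through[id(i, j)]))
      expect_equal(pp$seed_pairs_covered, unname(oracle$seed_pairs_covered[id(i, j)]))
    }
  }
})

test_that("total interior visitation matches enumeration on random graphs", {
  for (seed in 1:3) {
    g <- random_edge_graph(20, 0.15, seed = seed)
    net <- interaction_network(g$edges)
    nodes <- network_nodes(net)
    seeds <- nodes[seq(1, length(nodes), by = 4)]
    oracle <- oracle_path_profile(net$graph, seeds, nodes)
    mine <- vapply(nodes, function(v) path_profile(net, v, setdiff(seeds, v))$paths_through, numeric(1L))
    non_seed <- setdiff(nodes, seeds)
    expect_equal(mine[non_seed], oracle$paths_through[non_seed])
    expect_equal(sum(mine[non_seed]), sum(oracle$paths_through[non_seed]))
  }
})
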