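test_that("network generation hits exact sizes and is reproducible", {
  n1 <- generate_network(n_nodes = 100, n_edges = 300, rng_seed = 2)
  n2 <- generate_network(n_nodes = 100, n_edges = 300, rng_seed = 2)
  expect_equal(network_edges(n1), network_edges(n2))
  expect_equal(length(network_nodes(n1)), 100L)
  expect_equal(nrow(network_edges(n1)), 300L)
  expect_true(igraph::is_connected(n1$graph))
  # minimal edge budget yields a tree
  tree <- generate_network(n_nodes = 5, n_edges = 4, rng_seed = 1)
  expect_equal(nrow(network_edges(tree)), 4L)
  expect_true(igraph::is_connected(tree$graph))
  expect_error(generate_network(n_nodes = 10, n_edges = 3), "too few")
  expect_error(generate_network(n_nodes = 4, n_edges = 10), "node pairs")
})

test_that("preferential attachment produces heavy-tailed degrees", {
  ok <- vapply(1:20, function(s) {
    net <- generate_network(n_nodes = 100, n_edges = 300, rng_seed = s)
    deg <- igraph::degree(net$graph)
    max(deg) >= 3 * stats::median(deg)
  }, logical(1L))
  expect_true(all(ok))
})

test_that("scenarios are byte-identical for identical config and seed", {
  cfg <- scenario_config(rng_seed = 23)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scenario(generate_scenario(cfg), d1)
  write_scenario(generate_scenario(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)), label = f)
  }
  # and a different seed changes the network
  d3 <- withr::local_tempdir()
  write_scenario(generate_scenario(scenario_config(rng_seed = 24)), d3)
  expect_false(identical(
    readLines(file.path(d1, "network.tsv")),
    readLines(file.path(d3, "network.tsv"))
  ))
})

test_that("zero seed overlap makes the models' direct sets disjoint", {
  scn <- generate_scenario(scenario_config(seed_overlap_fraction = 0))
  expect_length(intersect(
    scn$truth$model_seeds$modelA$up,
    scn$truth$model_seeds$modelB$up
  ), 0)
  scn2 <- generate_scenario(scenario_config(seed_overlap_fraction = 1))
  expect_setequal(scn2$truth$model_seeds$modelA$up, scn2$truth$model_seeds$modelB$up)
})

test_that("every differential call is attributable to a planted cause", {
  scn <- generate_scenario(scenario_config())
  for (m in names(scn$stats)) {
    ds <- select_differential(scn$stats[[m]], model = m)
    truth <- scn$truth$model_seeds[[m]]
    # planted recovery at least 95%, and nothing called beyond the plant
    expect_gte(length(intersect(ds$up, truth$up)) / length(truth$up), 0.95)
    expect_gte(length(intersect(ds$down, truth$down)) / length(truth$down), 0.95)
    expect_length(setdiff(c(ds$up, ds$down), unlist(truth)), 0)
  }
})

test_that("hidden regulators stay out of the seed sets and inside pathways", {
  scn <- generate_scenario(scenario_config())
  tr <- scn$truth
  expect_length(intersect(tr$hidden_regulators, unlist(tr$model_seeds)), 0)
  planted_members <- unlist(scn$pathways$pathways[tr$planted_pathways])
  expect_true(all(tr$hidden_regulators %in% planted_members))
  # seeds are not members of any pathway (direct enrichment must be blind)
  all_members <- unlist(scn$pathways$pathways)
  expect_length(intersect(unlist(tr$model_seeds), all_members), 0)
})

test_that("a null scenario is calibrated", {
  cfg <- scenario_config(expr_lfc = 0, spike_fold = 1, rppa_effect = 0, rng_seed = 31)
  scn <- generate_scenario(cfg)
  # differential p-values are uniform
  ks <- stats::ks.test(scn$stats$modelA$pvalue, "punif")
  expect_gt(ks$p.value, 0.01)
  # false positive rate of the threshold rule is at most the p cut
  ds <- select_differential(scn$stats$modelA)
  expect_lte(length(c(ds$up, ds$down)) / nrow(scn$stats$modelA), 0.05)
  expect_length(scn$truth$rppa_up_truth, 0)
})

test_that("randomized PIT of the pathway test is uniform under its null", {
  # panel-conditional permutation null: fixed K up-calls assigned at random
  set.seed(41)
  N <- 120
  n <- 24
  K <- 35
  u <- vapply(1:200, function(i) {
    k <- stats::rhyper(1, K, N - K, n)
    p_ge <- pathway_hypergeom_test(hypergeom_input(k, K, n, N))
    p_gt <- if (k + 1 > min(K, n)) 0 else pathway_hypergeom_test(hypergeom_input(k + 1, K, n, N))
    p_gt + stats::runif(1) * (p_ge - p_gt)
  }, numeric(1L))
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
})
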