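test_that("multilayer modularity matches closed-form hand values", {
  tri <- two_triangles()
  net1 <- multilayer_network(array(tri, c(6, 6, 1)), gamma = 1, omega = 0)
  one <- matrix(1, 6, 1)
  comp <- matrix(c(1, 1, 1, 2, 2, 2), ncol = 1)

  # all nodes in one community: the null cancels the total weight
  expect_equal(multilayer_modularity(net1, one), 0)
  # partition by component: Q = 2 * (3/6 - (6/12)^2) = 0.5
  expect_equal(multilayer_modularity(net1, comp), 0.5)

  # two identical layers, omega = 1: Q = (12 + 12w) / (24 + 12w) = 2/3
  net2 <- multilayer_network(array(c(tri, tri), c(6, 6, 2)), omega = 1)
  expect_equal(multilayer_modularity(net2, cbind(comp, comp)), 2 / 3)
  # and the general omega expression at another coupling
  net3 <- multilayer_network(array(c(tri, tri), c(6, 6, 2)), omega = 2.5)
  expect_equal(multilayer_modularity(net3, cbind(comp, comp)),
               (12 + 12 * 2.5) / (24 + 12 * 2.5))

  # invariance under community relabeling
  relab <- matrix(c(7, 7, 7, 3, 3, 3), ncol = 1)
  expect_equal(multilayer_modularity(net1, relab), 0.5)

  expect_error(
    multilayer_modularity(multilayer_network(array(0, c(3, 3, 2)), omega = 0),
                          matrix(1, 3, 2)),
    "undefined")
})

test_that("single-layer quality agrees with igraph's modularity", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    a <- random_layer(8, density = 0.5, seed = seed)
    net <- multilayer_network(array(a, c(8, 8, 1)), omega = 0)
    res <- generalized_louvain(net, seed = seed)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(res$quality,
                 igraph::modularity(g, drop(res$labels),
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("generalized Louvain recovers planted structure exactly", {
  tri <- two_triangles()
  net1 <- multilayer_network(array(tri, c(6, 6, 1)), omega = 0)
  res <- generalized_louvain(net1, seed = 3)
  expect_equal(res$quality, 0.5)
  expect_equal(res$n_communities, 2)
  # components recovered up to relabeling
  lab <- drop(res$labels)
  expect_equal(length(unique(lab[1:3])), 1)
  expect_equal(length(unique(lab[4:6])), 1)
  expect_false(lab[1] == lab[4])
  # matches the exhaustive-search optimum
  expect_equal(res$quality, exhaustive_best_quality(net1))
})

test_that("Louvain equals exhaustive enumeration on small multilayer nets", {
  # 3 nodes x 2 layers, strong within-layer triangle ties, omega large:
  # constant-across-layers one-community partition is optimal
  tri3 <- matrix(1, 3, 3) - diag(3)
  net <- multilayer_network(array(c(tri3, tri3), c(3, 3, 2)), omega = 4)
  res <- generalized_louvain(net, seed = 1)
  best <- exhaustive_best_quality(net)
  expect_equal(res$quality, best, tolerance = 1e-12)
  expect_true(all(res$labels[, 1] == res$labels[, 2]))

  # battery of random instances with <= 6 node-layer copies
  cases <- list(
    list(R = 5, W = 1, omega = 0), list(R = 6, W = 1, omega = 0),
    list(R = 3, W = 2, omega = 0.5), list(R = 3, W = 2, omega = 2),
    list(R = 2, W = 3, omega = 1), list(R = 2, W = 2, omega = 0.3))
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    layers <- array(0, c(cs$R, cs$R, cs$W))
    for (w in seq_len(cs$W))
      layers[, , w] <- random_layer(cs$R, 0.7, seed = 100 * ci + w)
    net <- multilayer_network(layers, omega = cs$omega)
    best <- exhaustive_best_quality(net)
    got <- louvain_best(net, seeds = 1:5)
    expect_lte(got, best + 1e-12)
    expect_equal(got, best, tolerance = 1e-10)
  }
})

test_that("detection is deterministic and bounded below by singletons", {
  cfg <- synth_config(
    n_per_group = c(tdc = 1, adhd_unmedicated = 0, adhd_medicated = 0),
    n_regions = 12, n_timepoints = 45, master_seed = 14)
  st <- build_layer_stack(simulate_cohort(cfg)$timeseries[[1]])
  net <- multilayer_network(st)
  a1 <- generalized_louvain(net, seed = 99)
  a2 <- generalized_louvain(net, seed = 99)
  expect_identical(a1$labels, a2$labels)
  expect_identical(a1$quality, a2$quality)

  # returned quality equals the quality function evaluated on the labels
  expect_equal(a1$quality, multilayer_modularity(net, a1$labels),
               tolerance = 1e-12)

  d <- dim(net$layers)
  singletons <- matrix(seq_len(d[1] * d[3]), d[1], d[3])
  expect_gte(a1$quality, multilayer_modularity(net, singletons))
})

test_that("repeated detection derives reproducible independent runs", {
  tri <- two_triangles()
  net <- multilayer_network(array(c(tri, tri), c(6, 6, 2)), omega = 1)
  expect_length(detect_communities(net, n_reps = 1, master_seed = 1), 1)
  expect_error(detect_communities(net, n_reps = 0, master_seed = 1),
               "invalid")

  d1 <- detect_communities(net, n_reps = 5, master_seed = 8)
  d2 <- detect_communities(net, n_reps = 5, master_seed = 8)
  expect_identical(lapply(d1, `[[`, "labels"), lapply(d2, `[[`, "labels"))

  # well-separated planted structure: identical co-assignment in every run
  coassign <- function(lab) outer(drop(lab), drop(lab), `==`)
  mats <- lapply(d1, function(a) coassign(a$labels[, 1]))
  for (m in mats[-1]) expect_identical(m, mats[[1]])
})

test_that("stronger coupling increases label persistence across layers", {
  cfg <- synth_config(
    n_per_group = c(tdc = 1, adhd_unmedicated = 0, adhd_medicated = 0),
    n_regions = 12, n_timepoints = 60, n_states = 3,
    switch_rate = c(tdc = 0.3, adhd_unmedicated = 0.1, adhd_medicated = 0.2),
    master_seed = 15)
  st <- build_layer_stack(simulate_cohort(cfg)$timeseries[[1]])
  mean_flex <- vapply(c(0.1, 1, 20), function(om) {
    det <- detect_communities(multilayer_network(st, omega = om),
                              n_reps = 5, master_seed = 3)
    mean(mean_over_reps(det))
  }, numeric(1))
  expect_true(all(diff(mean_flex) <= 1e-9))
  # very large coupling locks labels: flexibility collapses toward zero
  expect_lt(mean_flex[3], 0.02)
})

test_that("zero-weight layers are tolerated when coupling is positive", {
  tri <- two_triangles()
  layers <- array(0, c(6, 6, 3))
  layers[, , 1] <- tri
  layers[, , 3] <- tri
  net <- multilayer_network(layers, omega = 1)  # middle layer empty
  res <- generalized_louvain(net, seed = 2)
  expect_equal(res$quality, multilayer_modularity(net, res$labels),
               tolerance = 1e-12)
  expect_true(is.finite(res$quality))
})
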