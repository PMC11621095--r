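test_that("clustering matches closed forms and triangle enumeration", {
  tri <- make_net(adj_from_edges(3, list(c(1, 2), c(1, 3), c(2, 3))))
  expect_equal(clustering_coefficient(tri)$Cp, 1.0)

  star <- make_net(adj_from_edges(5, lapply(2:5, function(j) c(1, j))))
  expect_equal(clustering_coefficient(star)$Cp, 0.0)

  g5 <- make_net(adj_from_edges(5, list(c(1, 2), c(1, 3), c(2, 3),
                                        c(3, 4), c(4, 5))))
  cc <- clustering_coefficient(g5)
  expect_equal(cc$nodal, c(1, 1, 1 / 3, 0, 0))
  expect_equal(cc$Cp, 7 / 15)
})

test_that("shortest paths agree with a Floyd-Warshall oracle", {
  k4 <- make_net(1 - diag(4))
  d4 <- shortest_path_lengths(k4)
  expect_equal(d4[row(d4) != col(d4)], rep(1, 12))

  path3 <- make_net(adj_from_edges(3, list(c(1, 2), c(2, 3))))
  expect_equal(shortest_path_lengths(path3)[1, 3], 2)

  set.seed(5)
  adj <- rand_adj(20, 0.15)
  expect_equal(shortest_path_lengths(make_net(adj)), fw_distances(adj),
               ignore_attr = TRUE)
})

test_that("characteristic path length averages connected pairs and warns on fragmentation", {
  expect_equal(characteristic_path_length(make_net(1 - diag(5))), 1.0)

  path3 <- make_net(adj_from_edges(3, list(c(1, 2), c(2, 3))))
  expect_equal(characteristic_path_length(path3), 4 / 3)

  two_k2 <- make_net(adj_from_edges(4, list(c(1, 2), c(3, 4))))
  expect_warning(lp <- characteristic_path_length(two_k2), "fragmented")
  expect_equal(lp, 1.0)

  empty <- make_net(matrix(0L, 3, 3))
  expect_error(characteristic_path_length(empty), "no edges")
})

test_that("efficiencies match closed forms and the induced-subgraph oracle", {
  expect_equal(global_efficiency(make_net(1 - diag(6))), 1.0)

  path3 <- make_net(adj_from_edges(3, list(c(1, 2), c(2, 3))))
  expect_equal(global_efficiency(path3), 5 / 6)

  iso <- make_net(adj_from_edges(4, list(c(1, 2), c(1, 3))))
  expect_equal(nodal_efficiency(iso)[4], 0)

  expect_equal(local_efficiency(make_net(1 - diag(4)))$Eloc, 1.0)
  star <- make_net(adj_from_edges(5, lapply(2:5, function(j) c(1, j))))
  expect_equal(local_efficiency(star)$Eloc, 0.0)

  g5 <- adj_from_edges(5, list(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(4, 5)))
  expect_equal(local_efficiency(make_net(g5))$nodal,
               brute_local_efficiency(g5)$nodal)
})

test_that("betweenness matches exhaustive path counting", {
  path3 <- make_net(adj_from_edges(3, list(c(1, 2), c(2, 3))))
  expect_equal(betweenness_centrality(path3), c(0, 1, 0))

  star5 <- make_net(adj_from_edges(5, lapply(2:5, function(j) c(1, j))))
  expect_equal(betweenness_centrality(star5)[1], 6)

  c4 <- make_net(adj_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4), c(1, 4))))
  expect_equal(betweenness_centrality(c4), rep(0.5, 4))

  set.seed(9)
  for (rep in 1:5) {
    adj <- rand_adj(8, 0.3)
    expect_equal(betweenness_centrality(make_net(adj)),
                 brute_betweenness(adj), tolerance = 1e-12)
  }
})

test_that("complete graphs are perfectly clustered and efficient for N = 3..8", {
  for (n in 3:8) {
    net <- make_net(1 - diag(n))
    expect_equal(clustering_coefficient(net)$Cp, 1.0)
    expect_equal(global_efficiency(net), 1.0)
    expect_equal(local_efficiency(net)$Eloc, 1.0)
  }
})

test_that("node relabeling permutes nodal metrics and fixes global ones", {
  set.seed(13)
  adj <- rand_adj(10, 0.3)
  perm <- sample(10)
  padj <- adj[perm, perm]
  net <- make_net(adj); pnet <- make_net(padj)

  expect_equal(clustering_coefficient(pnet)$nodal,
               clustering_coefficient(net)$nodal[perm])
  expect_equal(nodal_efficiency(pnet), nodal_efficiency(net)[perm])
  expect_equal(local_efficiency(pnet)$nodal,
               local_efficiency(net)$nodal[perm])
  expect_equal(betweenness_centrality(pnet),
               betweenness_centrality(net)[perm])
  expect_equal(clustering_coefficient(pnet)$Cp, clustering_coefficient(net)$Cp)
  expect_equal(suppressWarnings(characteristic_path_length(pnet)),
               suppressWarnings(characteristic_path_length(net)))
})

test_that("nodal means reproduce the global efficiencies exactly", {
  set.seed(17)
  for (rep in 1:5) {
    net <- make_net(rand_adj(12, 0.25))
    expect_equal(mean(nodal_efficiency(net)), global_efficiency(net),
                 tolerance = 1e-12)
    le <- local_efficiency(net)
    expect_equal(mean(le$nodal), le$Eloc, tolerance = 1e-12)
  }
})

test_that("degree-preserving nulls keep the degree sequence and are seeded", {
  set.seed(23)
  net <- make_net(rand_adj(15, 0.25))
  ens <- degree_preserving_nulls(net, n_nulls = 5, seed = 31,
                                 keep_graphs = TRUE)
  for (g in ens$graphs)
    expect_equal(igraph::degree(g), node_degree(net), ignore_attr = TRUE)

  ens2 <- degree_preserving_nulls(net, n_nulls = 5, seed = 31)
  expect_equal(ens$Cp_rand_mean, ens2$Cp_rand_mean)
  expect_equal(ens$Lp_rand_mean, ens2$Lp_rand_mean)

  expect_error(degree_preserving_nulls(make_net(adj_from_edges(3,
    list(c(1, 2))))), "at least 2 edges")
})

test_that("rewiring destroys lattice clustering", {
  lat <- make_net(ring_lattice_adj(30, 4))
  ens <- degree_preserving_nulls(lat, n_nulls = 20, seed = 7)
  expect_lt(ens$Cp_rand_mean, clustering_coefficient(lat)$Cp)
})

test_that("small-world indices behave on self-null and Watts-Strogatz graphs", {
  k5 <- make_net(1 - diag(5))
  expect_warning(ens <- degree_preserving_nulls(k5, n_nulls = 3, seed = 1),
                 "complete graph")
  sw <- small_world(k5, ens)
  expect_equal(sw$gamma, 1.0)
  expect_equal(sw$lambda, 1.0)
  expect_equal(sw$sigma, 1.0)

  set.seed(41)
  ws <- igraph::sample_smallworld(1, 90, 5, 0.1)
  net <- make_net(as.matrix(igraph::as_adjacency_matrix(ws)))
  ens_ws <- degree_preserving_nulls(net, n_nulls = 100, seed = 41)
  sw_ws <- small_world(net, ens_ws)
  expect_gt(sw_ws$sigma, 1)
  expect_equal(sw_ws$sigma, sw_ws$gamma / sw_ws$lambda, tolerance = 1e-12)
})

test_that("AUC is the trapezoidal integral over the sparsity grid", {
  grid <- sparsity_grid()
  expect_equal(metric_auc(rep(3, 47), grid), 3 * 0.46)
  expect_equal(metric_auc(rep(0, 47), grid), 0)
  expect_equal(metric_auc(seq(0, 1, length.out = 47), grid), 0.23)
  expect_error(metric_auc(rep(1, 46), grid), "one metric value per")
  expect_error(metric_auc(c(rep(1, 46), NA), grid), "non-finite")
})

test_that("metric and AUC tables have complete long-format structure", {
  set.seed(19)
  coh <- generate_cohort(cohort_spec(n_patients = 1, n_controls = 1,
                                     n_volumes = 60, seed = 19))
  conns <- lapply(coh$subjects, function(s) build_connectome(s$timeseries))
  names(conns) <- c("s1", "s2")
  grid <- sparsity_grid(0.1, 0.2, 0.05)
  mt <- metric_table(conns, grid, nodal = TRUE, n_nulls = 5, seed = 3)
  expect_setequal(unique(mt$metric),
                  c("Cp", "Lp", "Eglob", "Eloc", "gamma", "lambda", "sigma",
                    "degree", "efficiency", "betweenness", "local_efficiency"))
  auc <- auc_table(mt, grid)
  expect_equal(nrow(auc), 2 * (7 + 4 * 90))
  expect_error(auc_table(mt[-1, ], grid), "missing grid point")
})
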