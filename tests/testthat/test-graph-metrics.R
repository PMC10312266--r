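test_that("global efficiency matches hand values and conventions", {
  expect_equal(global_efficiency(complete_net(4)), 1)
  expect_equal(global_efficiency(binary_network(matrix(0L, 4, 4))), 0)
  expect_equal(global_efficiency(path3_net()), (1 + 1 + 0.5) / 3)
  expect_error(global_efficiency(binary_network(matrix(0L, 1, 1))), "at least 2")
})

test_that("local efficiency handles low-degree nodes and cliques", {
  expect_equal(local_efficiency(complete_net(4)), 1)
  expect_equal(local_efficiency(star_net(3)), 0)
  expect_equal(local_efficiency(triangle_net()), 1)
})

test_that("clustering coefficient matches triangle-count oracle", {
  expect_equal(clustering_coefficient(triangle_net()), 1)
  expect_equal(clustering_coefficient(star_net(3)), 0)
  # K4 minus one edge: degree-3 nodes sit in 2 triangles each
  a <- 1 - diag(4); a[3, 4] <- a[4, 3] <- 0
  k4e <- binary_network(a)
  expect_equal(clustering_coefficient(k4e), oracle_clustering(a))
  expect_equal(clustering_coefficient(k4e), (2 / 3 + 2 / 3 + 1 + 1) / 4)
})

test_that("characteristic path length averages over reachable pairs", {
  expect_equal(characteristic_path_length(complete_net(4)), 1)
  expect_equal(characteristic_path_length(path3_net()), 4 / 3)
  two_edges <- binary_network(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                                    c(0, 0, 0, 1), c(0, 0, 1, 0)))
  expect_equal(characteristic_path_length(two_edges), 1)
  expect_error(characteristic_path_length(two_edges, disconnected = "error"),
               "disconnected")
  expect_error(characteristic_path_length(binary_network(matrix(0L, 3, 3))),
               "undefined")
})

test_that("metrics agree with brute-force oracles on random small graphs", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(4:10, 1)
    net <- random_network(n, runif(1, 0.2, 0.8))
    a <- net$adjacency
    expect_equal(global_efficiency(net), oracle_global_eff(a))
    expect_equal(clustering_coefficient(net), oracle_clustering(a))
    expect_equal(local_efficiency(net), oracle_local_eff(a))
    lp <- oracle_path_length(a)
    if (is.na(lp)) {
      expect_error(characteristic_path_length(net))
    } else {
      expect_equal(characteristic_path_length(net), lp)
    }
  }
})

test_that("metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (rep in 1:20) {
    net <- random_network(sample(5:25, 1), runif(1, 0.15, 0.6))
    g <- igraph::graph_from_adjacency_matrix(net$adjacency,
                                             mode = "undirected")
    lt <- igraph::transitivity(g, type = "localundirected",
                               isolates = "zero")
    expect_equal(clustering_coefficient(net), mean(lt))
    expect_equal(global_efficiency(net),
                 igraph::global_efficiency(g, directed = FALSE))
  }
})

test_that("adding an edge never decreases global efficiency or degree", {
  set.seed(42)
  for (rep in 1:20) {
    net <- random_network(8, 0.3)
    zeros <- which(upper.tri(net$adjacency) & net$adjacency == 0,
                   arr.ind = TRUE)
    if (nrow(zeros) == 0) next
    pick <- zeros[sample(nrow(zeros), 1), ]
    a2 <- net$adjacency
    a2[pick[1], pick[2]] <- a2[pick[2], pick[1]] <- 1L
    net2 <- binary_network(a2)
    expect_gte(global_efficiency(net2), global_efficiency(net))
    expect_true(all(node_degrees(net2) >= node_degrees(net)))
  }
})

test_that("Louvain modularity finds planted structure and stays nonnegative", {
  lv <- modularity_louvain(two_cliques_net(4), n_restarts = 20, seed = 1)
  expect_equal(lv$Q, 0.5)
  expect_equal(lv$n_modules, 2)
  expect_equal(oracle_best_modularity(two_cliques_net(4)$adjacency), 0.5)

  lv5 <- modularity_louvain(complete_net(5), n_restarts = 20, seed = 1)
  expect_equal(lv5$Q, 0)
  expect_equal(lv5$n_modules, 1)

  expect_error(modularity_louvain(binary_network(matrix(0L, 3, 3))),
               "edgeless")
})

test_that("Louvain Q is invariant to node permutation and >= 0 on random graphs", {
  set.seed(9)
  net <- random_network(12, 0.3)
  perm <- sample(12)
  permuted <- binary_network(net$adjacency[perm, perm])
  q1 <- modularity_louvain(net, n_restarts = 50, seed = 3)$Q
  q2 <- modularity_louvain(permuted, n_restarts = 50, seed = 3)$Q
  expect_equal(q1, q2, tolerance = 1e-10)
  for (rep in 1:10) {
    r <- random_network(10, runif(1, 0.2, 0.7))
    if (n_edges(r) == 0) next
    expect_gte(modularity_louvain(r, n_restarts = 10, seed = rep)$Q, 0)
  }
})

test_that("Louvain with restarts attains the exhaustive-search optimum on tiny graphs", {
  set.seed(303)
  for (rep in 1:15) {
    net <- random_network(sample(5:7, 1), runif(1, 0.3, 0.7))
    if (n_edges(net) == 0) next
    lv <- modularity_louvain(net, n_restarts = 50, seed = rep)
    best <- max(0, oracle_best_modularity(net$adjacency))
    expect_equal(lv$Q, best, tolerance = 1e-10)
    # reported Q matches its own partition
    expect_equal(oracle_modularity(net$adjacency, lv$partition), lv$Q,
                 tolerance = 1e-10)
  }
})

test_that("degree-preserving rewiring keeps the exact degree sequence", {
  set.seed(21)
  net <- random_network(12, 0.35)
  cfg <- null_ensemble_config(n_nulls = 10, swaps_per_edge = 10, seed = 4)
  nulls <- degree_preserving_rewire(net, cfg)
  expect_length(nulls, 10)
  for (nl in nulls) {
    expect_identical(node_degrees(nl), node_degrees(net))
    expect_identical(n_edges(nl), n_edges(net))
  }
  # on a 6-node, 7-edge graph, 70 attempted swaps move at least one null
  set.seed(8)
  small <- random_network(6, 0.5)
  while (n_edges(small) != 7) small <- random_network(6, 0.5)
  nl <- degree_preserving_rewire(small, null_ensemble_config(5, 10, seed = 2))
  expect_true(any(vapply(nl, function(x)
    !identical(x$adjacency, small$adjacency), logical(1))))
  expect_error(degree_preserving_rewire(binary_network(matrix(0L, 3, 3))),
               "fewer than 2")
})

test_that("small-world metrics normalize to 1 on complete graphs and exceed 1 on cliquish ones", {
  cfg <- null_ensemble_config(n_nulls = 10, swaps_per_edge = 5, seed = 6)
  sw <- small_world_metrics(complete_net(6), cfg)
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)

  roc <- ring_of_cliques_net(6, 5)
  sw2 <- small_world_metrics(roc, null_ensemble_config(20, 10, seed = 7))
  expect_gt(sw2$gamma, 1)
  expect_equal(sw2$sigma, sw2$gamma / sw2$lambda)
})

test_that("a null of a network is itself unremarkable under normalization", {
  set.seed(31)
  net <- random_network(20, 0.25)
  nl <- degree_preserving_rewire(net, null_ensemble_config(1, 10, seed = 9))[[1]]
  sw <- small_world_metrics(nl, null_ensemble_config(50, 10, seed = 10))
  expect_equal(sw$gamma, 1, tolerance = 0.35) # sampling error only
})

test_that("metric_vector bundles components consistently", {
  net <- two_cliques_net(4)
  cfg <- null_ensemble_config(n_nulls = 5, swaps_per_edge = 5, seed = 2)
  mv <- metric_vector(net, cfg, louvain_restarts = 20, seed = 1)
  expect_named(mv, c("Cp", "Lp", "gamma", "lambda", "sigma", "Eg", "Eloc",
                     "Q", "Mn"))
  expect_equal(unname(mv["Cp"]), clustering_coefficient(net))
  expect_equal(unname(mv["Eg"]), global_efficiency(net))
  expect_equal(unname(mv["Eloc"]), local_efficiency(net))
  expect_equal(unname(mv["Q"]), 0.5)
  expect_equal(unname(mv["Mn"]), 2)
  expect_equal(unname(mv["sigma"]), unname(mv["gamma"] / mv["lambda"]))

  k4 <- metric_vector(complete_net(4), cfg, louvain_restarts = 5, seed = 1)
  expect_equal(unname(k4[c("Cp", "Lp", "Eg", "Eloc")]), c(1, 1, 1, 1))
})
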