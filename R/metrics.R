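#' Configuration for degree-preserving null ensembles
#'
#' @param n_nulls Number of rewired networks (default 100, the benchmark
#'   ensemble size).
#' @param swaps_per_edge Attempted double-edge swaps per edge (default 10).
#' @param seed Integer seed.
#' @return A `null_ensemble_config` list.
#' @export
null_ensemble_config <- function(n_nulls = 100L, swaps_per_edge = 10L,
                                 seed = 1L) {
  stopifnot(n_nulls >= 1, swaps_per_edge >= 1)
  structure(list(n_nulls = as.integer(n_nulls),
                 swaps_per_edge = as.integer(swaps_per_edge),
                 seed = as.integer(seed)),
            class = "null_ensemble_config")
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path length;
#' unreachable pairs contribute 0 (the "1/Inf = 0" convention). Measures
#' network integration; 1 for a complete graph, 0 for an edgeless one.
#'
#' @param net A [binary_network()] with at least 2 nodes.
#' @return Dimensionless value in \[0, 1\].
#' @export
global_efficiency <- function(net) {
  assert_network(net, min_nodes = 2L)
  cpp_global_efficiency(net$adjacency)
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbours (the node itself excluded); nodes with fewer than two
#' neighbours contribute 0. Measures fault-tolerant segregated processing.
#'
#' @param net A [binary_network()] with at least 2 nodes.
#' @return Dimensionless value in \[0, 1\].
#' @export
local_efficiency <- function(net) {
  assert_network(net, min_nodes = 2L)
  cpp_local_efficiency(net$adjacency)
}

#' Clustering coefficient (Watts-Strogatz)
#'
#' Mean over nodes of `2 * triangles_i / (k_i * (k_i - 1))`; nodes of degree
#' below 2 contribute 0.
#'
#' @param net A [binary_network()] with at least 3 nodes.
#' @return Dimensionless value in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  assert_network(net, min_nodes = 3L)
  cpp_clustering(net$adjacency)
}

#' Characteristic path length
#'
#' Mean shortest-path length over reachable ordered node pairs only, so the
#' metric stays finite on near-connected graphs. Set
#' `disconnected = "error"` to insist on full connectivity instead.
#'
#' @param net A [binary_network()].
#' @param disconnected `"reachable"` (default: average over reachable pairs)
#'   or `"error"` (fail when any pair is unreachable).
#' @return Mean hop count (>= 1 when any edge exists).
#' @export
characteristic_path_length <- function(net,
                                       disconnected = c("reachable", "error")) {
  assert_network(net, min_nodes = 2L)
  disconnected <- match.arg(disconnected)
  sc <- cpp_path_length(net$adjacency)
  n <- n_nodes(net)
  if (sc[2] == 0) stop("no reachable node pair: path length undefined")
  if (disconnected == "error" && sc[2] < n * (n - 1))
    stop("network is disconnected and disconnected = \"error\"")
  sc[1] / sc[2]
}

#' Louvain modularity with restarts
#'
#' Runs the Louvain community-detection heuristic `n_restarts` times with
#' distinct sub-seeds and keeps the partition with maximal Newman-Girvan
#' modularity `Q = sum_c (e_c / m - (d_c / 2m)^2)`. Ties are broken by the
#' first-found partition under the seeded restart order, and the one-module
#' partition (Q = 0) is returned if no restart improves on it, so the
#' reported Q is never negative.
#'
#' @param net A [binary_network()] with at least one edge.
#' @param n_restarts Number of seeded restarts (default 100).
#' @param seed Integer seed.
#' @return List with `Q`, `partition` (named integer vector, modules numbered
#'   by first appearance) and `n_modules`.
#' @export
modularity_louvain <- function(net, n_restarts = 100L, seed = 1L) {
  assert_network(net)
  if (n_edges(net) < 1L) stop("modularity is undefined for an edgeless network")
  res <- cpp_louvain(net$adjacency, as.integer(n_restarts), as.integer(seed))
  partition <- res$membership
  names(partition) <- net$node_labels
  list(Q = res$Q, partition = partition, n_modules = res$n_modules)
}

#' Degree-preserving rewired null networks
#'
#' Generates an ensemble of random networks with exactly the same degree
#' sequence, node count and edge count as the input, by repeated double-edge
#' swaps (`swaps_per_edge * edge count` attempted swaps each).
#'
#' @param net A [binary_network()] with at least 2 independent edges.
#' @param cfg A [null_ensemble_config()].
#' @return List of `cfg$n_nulls` [binary_network()] objects.
#' @export
degree_preserving_rewire <- function(net, cfg = null_ensemble_config()) {
  assert_network(net)
  m <- n_edges(net)
  if (m < 2L) stop("cannot rewire a network with fewer than 2 edges")
  attempts <- cfg$swaps_per_edge * m
  lapply(seq_len(cfg$n_nulls), function(k) {
    adj <- cpp_rewire(net$adjacency, attempts,
                      as.integer((cfg$seed + k * 1000003L) %% .Machine$integer.max))
    binary_network(adj, net$node_labels)
  })
}

#' Small-world metrics normalized by degree-preserving nulls
#'
#' `gamma = Cp / mean(Cp_null)`, `lambda = Lp / mean(Lp_null)`,
#' `sigma = gamma / lambda`. `sigma > 1` indicates a small-world regime.
#'
#' @param net A [binary_network()].
#' @param cfg A [null_ensemble_config()]; its ensemble normalizes the metrics.
#' @param nulls Optional pre-computed null list (to reuse across metrics).
#' @return List with `gamma`, `lambda`, `sigma`, and the null means.
#' @export
small_world_metrics <- function(net, cfg = null_ensemble_config(),
                                nulls = NULL) {
  assert_network(net, min_nodes = 3L)
  if (is.null(nulls)) nulls <- degree_preserving_rewire(net, cfg)
  cp <- clustering_coefficient(net)
  lp <- characteristic_path_length(net)
  cp_null <- mean(vapply(nulls, clustering_coefficient, numeric(1)))
  lp_null <- mean(vapply(nulls, characteristic_path_length, numeric(1)))
  if (cp_null <= 0 || lp_null <= 0)
    stop("null ensemble has zero mean clustering or path length")
  gamma <- cp / cp_null
  lambda <- lp / lp_null
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       cp_null = cp_null, lp_null = lp_null)
}

#' Full 9-metric topological profile of a network
#'
#' Bundles the small-world metrics (Cp, Lp, gamma, lambda, sigma), the
#' efficiency metrics (Eg, Eloc) and the modularity metrics (Q, Mn, both from
#' the same best Louvain partition) into one named vector.
#'
#' @param net A [binary_network()].
#' @param cfg A [null_ensemble_config()] for the normalized metrics.
#' @param louvain_restarts Restarts for the modularity metrics (default 100).
#' @param seed Seed for the Louvain restarts.
#' @return Named numeric vector with elements
#'   `Cp, Lp, gamma, lambda, sigma, Eg, Eloc, Q, Mn`.
#' @export
metric_vector <- function(net, cfg = null_ensemble_config(),
                          louvain_restarts = 100L, seed = 1L) {
  sw <- small_world_metrics(net, cfg)
  lv <- modularity_louvain(net, n_restarts = louvain_restarts, seed = seed)
  c(Cp = clustering_coefficient(net),
    Lp = characteristic_path_length(net),
    gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma,
    Eg = global_efficiency(net), Eloc = local_efficiency(net),
    Q = lv$Q, Mn = as.numeric(lv$n_modules))
}
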