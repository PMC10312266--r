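#' Trade-off model specification
#'
#' Defines which efficiency objective a trade-off model optimizes against
#' wiring cost. The three models are:
#' \describe{
#'   \item{dual}{cost vs integration: `F_e = 1 - Eg`}
#'   \item{tri_eloc}{cost vs integration + segregation as local efficiency:
#'     `F_e = w_Eloc (1 - Eg) + (1 - w_Eloc)(1 - Eloc)`}
#'   \item{tri_q}{cost vs integration + segregation as modularity:
#'     `F_e = w_Q (1 - Eg) + (1 - w_Q)(1 - Q)`}
#' }
#' Smaller `F_e` means better communication efficiency, so both objectives
#' are minimized. The default weights (`w_Eloc = 0.9`, `w_Q = 0.8`) are the
#' settings that recover the empirical connectome best.
#'
#' @param name One of `"dual"`, `"tri_eloc"`, `"tri_q"`.
#' @param w_Eloc Weight on integration in the tri_eloc model, in (0, 1).
#' @param w_Q Weight on integration in the tri_q model, in (0, 1).
#' @param louvain_restarts Restarts for the in-loop Q evaluation (default 5;
#'   the final reported metrics use the full 100-restart policy).
#' @param seed Integer seed for the stochastic Q evaluation.
#' @return A `tradeoff_model` list.
#' @export
tradeoff_model <- function(name = c("dual", "tri_eloc", "tri_q"),
                           w_Eloc = 0.9, w_Q = 0.8,
                           louvain_restarts = 5L, seed = 1L) {
  name <- match.arg(name)
  if (w_Eloc <= 0 || w_Eloc >= 1 || w_Q <= 0 || w_Q >= 1)
    stop("weights must lie strictly inside (0, 1)")
  structure(list(name = name, w_Eloc = w_Eloc, w_Q = w_Q,
                 louvain_restarts = as.integer(louvain_restarts),
                 seed = as.integer(seed)),
            class = "tradeoff_model")
}

model_code <- function(spec) {
  switch(spec$name, dual = 1L, tri_eloc = 2L, tri_q = 3L)
}

model_weight <- function(spec) {
  switch(spec$name, dual = NA_real_, tri_eloc = spec$w_Eloc, tri_q = spec$w_Q)
}

#' Wiring cost of a network
#'
#' Sum of Euclidean distances (mm) between centroids of connected region
#' pairs: the material-cost proxy `F_c`.
#'
#' @param net A [binary_network()].
#' @param geom A [region_geometry()] matching the network's node count.
#' @return Cost in mm (>= 0; 0 for an edgeless network).
#' @export
wiring_cost <- function(net, geom) {
  assert_network(net)
  assert_geometry_match(net, geom)
  sum(geom$distance[net$adjacency == 1L]) / 2
}

#' Efficiency objective of a trade-off model
#'
#' Returns `F_e` under the given model (see [tradeoff_model()]); smaller
#' values indicate better efficiency. For `tri_q` the modularity term is the
#' best-of-restarts Louvain Q with the model's seeded restart policy; an
#' edgeless network raises an error here (the evolution engine instead
#' assigns such genomes the worst value 1 so the optimizer can proceed).
#'
#' @param net A [binary_network()].
#' @param spec A [tradeoff_model()].
#' @return Dimensionless value in \[0, 1\].
#' @export
efficiency_objective <- function(net, spec = tradeoff_model()) {
  assert_network(net, min_nodes = 2L)
  eg <- global_efficiency(net)
  switch(spec$name,
    dual = 1 - eg,
    tri_eloc = spec$w_Eloc * (1 - eg) +
      (1 - spec$w_Eloc) * (1 - local_efficiency(net)),
    tri_q = {
      if (n_edges(net) < 1L)
        stop("tri_q objective is undefined for an edgeless network")
      q <- modularity_louvain(net, n_restarts = spec$louvain_restarts,
                              seed = spec$seed)$Q
      spec$w_Q * (1 - eg) + (1 - spec$w_Q) * (1 - q)
    })
}

#' Evaluate a network under a trade-off model
#'
#' @param net A [binary_network()].
#' @param geom A [region_geometry()].
#' @param spec A [tradeoff_model()].
#' @return An `objective_pair` list with `F_c` (mm), `F_e` and
#'   `efficiency_index = 1 - F_e`.
#' @export
evaluate_network <- function(net, geom, spec = tradeoff_model()) {
  fc <- wiring_cost(net, geom)
  fe <- efficiency_objective(net, spec)
  structure(list(F_c = fc, F_e = fe, efficiency_index = 1 - fe),
            class = "objective_pair")
}

#' Pareto dominance between two objective pairs
#'
#' `a` dominates `b` iff `a` is no worse in both minimized objectives
#' (`F_c`, `F_e`) and strictly better in at least one.
#'
#' @param a,b `objective_pair` objects or lists with `F_c` and `F_e`.
#' @return Logical.
#' @export
dominates <- function(a, b) {
  (a$F_c <= b$F_c && a$F_e <= b$F_e) && (a$F_c < b$F_c || a$F_e < b$F_e)
}
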