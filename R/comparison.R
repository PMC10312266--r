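#' Recovery rate between a synthetic and an empirical network
#'
#' Over the off-diagonal upper triangle, `R1` is the fraction of empirical
#' edges also present in the synthetic network and `R0` the fraction of
#' empirical non-edges also absent. The summary rate `R` combines the two;
#' the default is the geometric mean `sqrt(R0 * R1)` (the raw product and
#' the arithmetic mean are available via `combine`).
#'
#' @param synthetic,empirical [binary_network()] objects with the same node
#'   count (and ordering).
#' @param combine `"geometric"` (default), `"product"` or `"mean"`.
#' @return A `recovery_report` list with `R`, `R0`, `R1` and the entry counts.
#' @export
recovery_rate <- function(synthetic, empirical,
                          combine = c("geometric", "product", "mean")) {
  combine <- match.arg(combine)
  assert_network(synthetic); assert_network(empirical)
  if (n_nodes(synthetic) != n_nodes(empirical))
    stop("networks must have the same node count")
  ut <- upper.tri(empirical$adjacency)
  e <- empirical$adjacency[ut]
  s <- synthetic$adjacency[ut]
  n1 <- sum(e == 1L); n0 <- sum(e == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("empirical network must contain both edges and non-edges")
  r1 <- sum(s[e == 1L] == 1L) / n1
  r0 <- sum(s[e == 0L] == 0L) / n0
  r <- switch(combine,
              geometric = sqrt(r0 * r1),
              product = r0 * r1,
              mean = (r0 + r1) / 2)
  structure(list(R = r, R0 = r0, R1 = r1, n_ones = n1, n_zeros = n0,
                 combine = combine),
            class = "recovery_report")
}

#' Recovery rates within Euclidean distance bins
#'
#' Node pairs are assigned to the distance bin containing their centroid
#' distance (left-closed, right-open; the last regular bin is closed). Bins
#' lacking either empirical edges or non-edges are reported as missing
#' (`NA`), not 0. Pairs beyond the last edge fall into a flagged overflow
#' bin.
#'
#' @param synthetic,empirical [binary_network()] objects.
#' @param geom A [region_geometry()] matching both networks.
#' @param bin_edges Bin boundaries in mm (default 0-120 by 20).
#' @param combine Combination rule passed to [recovery_rate()].
#' @return A `distance_bin_report` list with `bin_edges`, per-bin `R`, `R0`,
#'   `R1`, pair counts, and `overflow` (recovery among pairs beyond the last
#'   edge, `NA` if none).
#' @export
distance_binned_recovery <- function(synthetic, empirical, geom,
                                     bin_edges = seq(0, 120, by = 20),
                                     combine = c("geometric", "product",
                                                 "mean")) {
  combine <- match.arg(combine)
  assert_geometry_match(empirical, geom)
  if (n_nodes(synthetic) != n_nodes(empirical))
    stop("networks must have the same node count")
  ut <- upper.tri(empirical$adjacency)
  e <- empirical$adjacency[ut]
  s <- synthetic$adjacency[ut]
  d <- geom$distance[ut]
  n_bins <- length(bin_edges) - 1L
  bin <- findInterval(d, bin_edges, rightmost.closed = TRUE)
  bin[bin > n_bins] <- n_bins + 1L # overflow
  rate_in <- function(sel) {
    n1 <- sum(e[sel] == 1L); n0 <- sum(e[sel] == 0L)
    if (n1 == 0L || n0 == 0L)
      return(c(R = NA_real_, R0 = NA_real_, R1 = NA_real_, n = sum(sel)))
    r1 <- sum(s[sel][e[sel] == 1L] == 1L) / n1
    r0 <- sum(s[sel][e[sel] == 0L] == 0L) / n0
    r <- switch(combine, geometric = sqrt(r0 * r1), product = r0 * r1,
                mean = (r0 + r1) / 2)
    c(R = r, R0 = r0, R1 = r1, n = sum(sel))
  }
  per_bin <- t(vapply(seq_len(n_bins), function(b) rate_in(bin == b),
                      numeric(4)))
  overflow_n <- sum(bin == n_bins + 1L)
  overflow <- if (overflow_n > 0) {
    warning(sprintf("%d node pairs exceed the last distance bin edge (%g mm)",
                    overflow_n, bin_edges[length(bin_edges)]))
    rate_in(bin == n_bins + 1L)
  } else c(R = NA_real_, R0 = NA_real_, R1 = NA_real_, n = 0)
  structure(list(bin_edges = bin_edges,
                 per_bin_R = unname(per_bin[, "R"]),
                 per_bin_R0 = unname(per_bin[, "R0"]),
                 per_bin_R1 = unname(per_bin[, "R1"]),
                 per_bin_n = unname(per_bin[, "n"]),
                 overflow = overflow, combine = combine),
            class = "distance_bin_report")
}

#' Area under the binned recovery curve at middle/long distances
#'
#' Trapezoidal area of the per-bin recovery rates plotted at the bin
#' midpoints, restricted to bins whose lower edge is at least
#' `min_distance` (default 40 mm, i.e. midpoints 50/70/90/110 mm for the
#' standard bins). A rectangle (bar) sum over the bin widths is available
#' via `method = "rectangle"`.
#'
#' @param report A `distance_bin_report` from [distance_binned_recovery()].
#' @param min_distance Lower distance cutoff in mm.
#' @param method `"trapezoid"` (default) or `"rectangle"`.
#' @return AUC in mm x dimensionless units.
#' @export
bin_auc <- function(report, min_distance = 40,
                    method = c("trapezoid", "rectangle")) {
  method <- match.arg(method)
  edges <- report$bin_edges
  lo <- edges[-length(edges)]
  mids <- (edges[-length(edges)] + edges[-1]) / 2
  keep <- lo >= min_distance
  r <- report$per_bin_R[keep]
  mids <- mids[keep]
  if (any(is.na(r))) stop("bins above min_distance contain missing values")
  if (method == "rectangle")
    return(sum(r * diff(edges)[keep]))
  if (length(r) < 2) stop("need at least 2 valid bins for a trapezoid AUC")
  sum((r[-1] + r[-length(r)]) / 2 * diff(mids))
}

#' Filter an archive to a wiring-cost range
#'
#' Keeps the archive members whose cost objective lies within
#' `[cost_min, cost_max]` (endpoints inclusive), typically the cost range of
#' the individual empirical networks, so that topological comparisons are
#' not confounded by cost.
#'
#' @param archive A `pareto_archive`.
#' @param cost_min,cost_max Cost bounds in mm.
#' @return A filtered `pareto_archive` (possibly empty).
#' @export
cost_range_filter <- function(archive, cost_min, cost_max) {
  if (cost_min > cost_max) stop("cost_min must not exceed cost_max")
  keep <- which(archive$objectives$F_c >= cost_min &
                  archive$objectives$F_c <= cost_max)
  out <- archive
  out$genomes <- archive$genomes[, keep, drop = FALSE]
  out$objectives <- archive$objectives[keep, , drop = FALSE]
  rownames(out$objectives) <- NULL
  out
}

#' Topological dissimilarity to the empirical centroid
#'
#' Z-scores each topological metric over the pooled set of all synthetic and
#' empirical networks, computes the empirical centroid as the mean
#' normalized empirical profile, and reports each synthetic network's
#' Euclidean distance to that centroid. Metrics with zero spread over the
#' pool are excluded and flagged.
#'
#' @param synthetic_vectors Matrix/data frame of synthetic networks'
#'   metric profiles (rows = networks, columns = metrics, as from
#'   [metric_vector()]).
#' @param empirical_vectors Matrix/data frame of empirical networks'
#'   profiles with the same columns.
#' @return A `dissimilarity_report` list with `per_network_distance`,
#'   `empirical_centroid`, the pooled `normalization` (mean/sd per metric)
#'   and `excluded_metrics`.
#' @export
topological_dissimilarity <- function(synthetic_vectors, empirical_vectors) {
  syn <- as.matrix(synthetic_vectors)
  emp <- as.matrix(empirical_vectors)
  if (ncol(syn) != ncol(emp)) stop("metric columns must match")
  pool <- rbind(syn, emp)
  if (nrow(pool) < 2) stop("need at least 2 networks for z-scoring")
  mu <- colMeans(pool)
  sdv <- apply(pool, 2, stats::sd)
  excluded <- colnames(pool)[sdv == 0 | is.na(sdv)]
  keep <- which(sdv > 0 & !is.na(sdv))
  if (length(keep) == 0) stop("every metric has zero spread")
  z_syn <- scale(syn[, keep, drop = FALSE], center = mu[keep],
                 scale = sdv[keep])
  z_emp <- scale(emp[, keep, drop = FALSE], center = mu[keep],
                 scale = sdv[keep])
  centroid <- colMeans(z_emp)
  dists <- sqrt(rowSums(sweep(z_syn, 2, centroid)^2))
  structure(list(per_network_distance = unname(dists),
                 empirical_centroid = centroid,
                 normalization = list(mean = mu[keep], sd = sdv[keep]),
                 excluded_metrics = excluded),
            class = "dissimilarity_report")
}
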