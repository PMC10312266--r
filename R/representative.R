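#' Select the representative network of an archive
#'
#' The representative network of a trade-off model is the cost-filtered
#' archive member with the highest recovery rate against the group-level
#' empirical network; ties are broken by lower cost objective and then by
#' lexicographic genome order (deterministic).
#'
#' @param archive A `pareto_archive`.
#' @param empirical Group-level empirical [binary_network()].
#' @param cost_min,cost_max Cost range to filter to before selection.
#' @param combine Recovery combination rule (see [recovery_rate()]).
#' @return The selected [binary_network()], with attributes `R` and
#'   `objectives` (its objective row).
#' @export
select_representative <- function(archive, empirical, cost_min = -Inf,
                                  cost_max = Inf,
                                  combine = c("geometric", "product",
                                              "mean")) {
  combine <- match.arg(combine)
  filtered <- cost_range_filter(archive, cost_min, cost_max)
  if (archive_size(filtered) == 0)
    stop("no archive member falls in the requested cost range")
  nets <- archive_networks(filtered)
  rs <- vapply(nets, function(nt)
    recovery_rate(nt, empirical, combine = combine)$R, numeric(1))
  best_r <- max(rs)
  cand <- which(rs == best_r)
  if (length(cand) > 1) {
    fc <- filtered$objectives$F_c[cand]
    cand <- cand[fc == min(fc)]
  }
  if (length(cand) > 1) {
    keys <- apply(filtered$genomes[, cand, drop = FALSE], 2,
                  paste, collapse = "")
    cand <- cand[order(keys)][1]
  } else cand <- cand[1]
  out <- nets[[cand]]
  attr(out, "R") <- best_r
  attr(out, "objectives") <- filtered$objectives[cand, ]
  out
}

#' Partition agreement via label-matched Cohen's kappa
#'
#' Aligns the module labels of `p2` to those of `p1` by greedy one-to-one
#' maximum-overlap matching on the contingency table (unmatched modules get
#' fresh labels), then computes Cohen's kappa on the aligned label vectors.
#' Kappa is 1 iff the partitions are identical up to relabelling.
#'
#' @param p1,p2 Node-to-module maps (integer/factor vectors over the same
#'   node set; names, if present, must agree).
#' @return A `partition_agreement` list with `kappa`, `matched_label_map`
#'   and the `contingency` table.
#' @export
partition_kappa <- function(p1, p2) {
  if (length(p1) != length(p2))
    stop("partitions must cover the same node set")
  if (!is.null(names(p1)) && !is.null(names(p2)) &&
      !identical(names(p1), names(p2)))
    stop("partition node names do not match")
  f1 <- as.integer(factor(p1)); f2 <- as.integer(factor(p2))
  tab <- table(f1, f2)
  # greedy one-to-one matching by descending overlap
  ord <- order(-as.vector(tab))
  used1 <- logical(nrow(tab)); used2 <- logical(ncol(tab))
  map <- integer(ncol(tab)) # p2 module -> aligned label (p1 module space)
  for (k in ord) {
    if (tab[k] == 0) break
    i <- (k - 1) %% nrow(tab) + 1
    j <- (k - 1) %/% nrow(tab) + 1
    if (!used1[i] && !used2[j]) {
      map[j] <- i
      used1[i] <- TRUE; used2[j] <- TRUE
    }
  }
  fresh <- max(nrow(tab), ncol(tab)) + seq_len(sum(map == 0))
  map[map == 0] <- fresh
  aligned <- map[f2]
  # Cohen's kappa on (f1, aligned)
  levs <- sort(unique(c(f1, aligned)))
  a <- factor(f1, levels = levs); b <- factor(aligned, levels = levs)
  ct <- table(a, b)
  n <- sum(ct)
  po <- sum(diag(ct)) / n
  pe <- sum(rowSums(ct) * colSums(ct)) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  structure(list(kappa = kappa, matched_label_map = map, contingency = tab),
            class = "partition_agreement")
}

#' Correlation of nodal degree between two networks
#'
#' @param a,b [binary_network()] objects over the same node ordering.
#' @return List with Pearson `r` and two-sided `p`.
#' @export
degree_correlation <- function(a, b) {
  if (n_nodes(a) != n_nodes(b))
    stop("networks must have the same node count")
  da <- node_degrees(a); db <- node_degrees(b)
  if (stats::sd(da) == 0 || stats::sd(db) == 0)
    stop("degree correlation undefined: zero variance in a degree vector")
  ct <- stats::cor.test(da, db, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Identify hub regions by degree centrality
#'
#' Ranks nodes by descending degree and takes the top
#' `floor(top_fraction * N)` as hubs (18 of 90 at the default 20%). Ties at
#' the cutoff are broken by node index; a fully tied (regular) network is
#' flagged.
#'
#' @param net A [binary_network()] with at least 5 nodes.
#' @param top_fraction Fraction of nodes to select (default 0.20).
#' @return A `hub_report` list with `hub_set` (labels), `hub_index`,
#'   `threshold_rank` and `fully_tied`.
#' @export
identify_hubs <- function(net, top_fraction = 0.20) {
  assert_network(net, min_nodes = 5L)
  deg <- node_degrees(net)
  n_hubs <- floor(top_fraction * n_nodes(net))
  ord <- order(-deg, seq_along(deg))
  hub_index <- ord[seq_len(n_hubs)]
  structure(list(hub_set = net$node_labels[hub_index],
                 hub_index = hub_index,
                 threshold_rank = n_hubs,
                 fully_tied = length(unique(deg)) == 1L),
            class = "hub_report")
}

#' Count overlapping hubs between two hub reports
#'
#' @param h1,h2 `hub_report` objects over the same node universe.
#' @return Integer overlap count.
#' @export
hub_overlap <- function(h1, h2) {
  length(intersect(h1$hub_set, h2$hub_set))
}

attack_fractions <- seq(0.1, 0.9, by = 0.1)

eval_remaining <- function(adj, removed_idx) {
  keep <- setdiff(seq_len(nrow(adj)), removed_idx)
  if (length(keep) < 2) return(c(Eg = 0, Eloc = 0))
  sub <- adj[keep, keep, drop = FALSE]
  c(Eg = cpp_global_efficiency(sub), Eloc = cpp_local_efficiency(sub))
}

#' Random node-attack curve
#'
#' For each removal fraction in 0.1..0.9, removes `round(f * N)` uniformly
#' chosen nodes (cumulatively within each repetition) and recomputes the
#' raw global and local efficiency on the remaining induced subgraph;
#' reports the mean and standard deviation over repetitions.
#'
#' @param net A [binary_network()].
#' @param repetitions Number of random removal orders (default 100).
#' @param seed Integer seed.
#' @return An `attack_curve` list with `removal_fractions`, `preserved_Eg`,
#'   `preserved_Eloc`, their standard deviations, and `repetitions`.
#' @export
random_attack <- function(net, repetitions = 100L, seed = 1L) {
  assert_network(net)
  stopifnot(repetitions >= 1)
  n <- n_nodes(net)
  adj <- net$adjacency
  res <- with_local_seed(seed, {
    lapply(seq_len(repetitions), function(rep) {
      ord <- sample.int(n)
      t(vapply(attack_fractions, function(f)
        eval_remaining(adj, ord[seq_len(round(f * n))]), numeric(2)))
    })
  })
  eg <- vapply(res, function(m) m[, "Eg"], numeric(length(attack_fractions)))
  el <- vapply(res, function(m) m[, "Eloc"], numeric(length(attack_fractions)))
  structure(list(removal_fractions = attack_fractions,
                 preserved_Eg = rowMeans(eg),
                 preserved_Eloc = rowMeans(el),
                 sd_Eg = apply(eg, 1, stats::sd),
                 sd_Eloc = apply(el, 1, stats::sd),
                 repetitions = as.integer(repetitions), mode = "random"),
            class = "attack_curve")
}

#' Targeted node-attack curve
#'
#' Removes nodes in descending degree order (ties by node index). The
#' default static mode ranks by initial degree; the adaptive mode
#' recomputes degrees on the remaining subgraph after each removal. Raw
#' global and local efficiency are recomputed at each fraction grid point.
#'
#' @param net A [binary_network()].
#' @param adaptive Recompute degrees after each removal?
#' @return An `attack_curve` list (deterministic; `repetitions = 1`).
#' @export
targeted_attack <- function(net, adaptive = FALSE) {
  assert_network(net)
  n <- n_nodes(net)
  adj <- net$adjacency
  if (!adaptive) {
    ord <- order(-node_degrees(net), seq_len(n))
  } else {
    ord <- integer(0)
    alive <- seq_len(n)
    a <- adj
    for (k in seq_len(n)) {
      deg <- rowSums(a)
      pick <- which.max(deg) # first index among ties
      ord <- c(ord, alive[pick])
      alive <- alive[-pick]
      a <- a[-pick, -pick, drop = FALSE]
    }
  }
  vals <- t(vapply(attack_fractions, function(f)
    eval_remaining(adj, ord[seq_len(round(f * n))]), numeric(2)))
  structure(list(removal_fractions = attack_fractions,
                 preserved_Eg = vals[, "Eg"], preserved_Eloc = vals[, "Eloc"],
                 sd_Eg = rep(0, length(attack_fractions)),
                 sd_Eloc = rep(0, length(attack_fractions)),
                 repetitions = 1L, removal_order = ord,
                 mode = if (adaptive) "targeted_adaptive" else "targeted"),
            class = "attack_curve")
}

#' Area under an attack curve
#'
#' Trapezoidal area of the raw preserved-efficiency curves over the removal
#' fraction axis (0.1 to 0.9).
#'
#' @param curve An `attack_curve`.
#' @return List with `auc_Eg` and `auc_Eloc`.
#' @export
attack_auc <- function(curve) {
  f <- curve$removal_fractions
  if (any(is.na(curve$preserved_Eg)) || any(is.na(curve$preserved_Eloc)))
    stop("attack curve has missing grid points")
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(f))
  list(auc_Eg = trap(curve$preserved_Eg),
       auc_Eloc = trap(curve$preserved_Eloc))
}
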