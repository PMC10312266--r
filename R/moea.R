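#' Evolution configuration for the network NSGA-II
#'
#' Defaults follow the reference optimization protocol: population 200,
#' initial edge density 0.1, uniform crossover with per-entry swap
#' probability 0.5, per-entry mutation probability 0.1, at most 2000
#' generations with a 20-generation stall rule (< 5% of individuals changed
#' or < 0.1% relative change of both mean objectives), and 30 independent
#' runs whose Pareto sets are merged.
#'
#' @param population_size Individuals per generation (default 200).
#' @param init_density Probability that an initial genome entry is 1.
#' @param swap_probability Per-entry swap probability in uniform crossover.
#' @param flip_probability Per-entry flip probability in mutation.
#' @param max_generations Hard generation cap (default 2000).
#' @param stall_generations Consecutive stable generations required to stop.
#' @param change_fraction_threshold Population-turnover stall threshold.
#' @param objective_delta_threshold Relative mean-objective stall threshold.
#' @param n_runs Independent runs to merge (default 30).
#' @param seed Master seed; per-run seeds are derived from it.
#' @return An `evolution_config` list.
#' @export
evolution_config <- function(population_size = 200L, init_density = 0.1,
                             swap_probability = 0.5, flip_probability = 0.1,
                             max_generations = 2000L, stall_generations = 20L,
                             change_fraction_threshold = 0.05,
                             objective_delta_threshold = 0.001,
                             n_runs = 30L, seed = 1L) {
  probs <- c(init_density, swap_probability, flip_probability)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  stopifnot(population_size >= 1, max_generations >= 1,
            stall_generations >= 1, n_runs >= 1)
  structure(list(population_size = as.integer(population_size),
                 init_density = init_density,
                 swap_probability = swap_probability,
                 flip_probability = flip_probability,
                 max_generations = as.integer(max_generations),
                 stall_generations = as.integer(stall_generations),
                 change_fraction_threshold = change_fraction_threshold,
                 objective_delta_threshold = objective_delta_threshold,
                 n_runs = as.integer(n_runs), seed = as.integer(seed)),
            class = "evolution_config")
}

#' Initialize a population of network genomes
#'
#' Each genome is the upper triangle of an N x N adjacency matrix; entries
#' are independently 1 with probability `cfg$init_density`. Uses the current
#' RNG state (seed externally, or rely on [run_evolution()]'s seeding).
#'
#' @param cfg An [evolution_config()].
#' @param n_nodes Node count N (>= 2).
#' @return Integer 0/1 matrix with `N(N-1)/2` rows, one column per individual.
#' @export
initialize_population <- function(cfg, n_nodes) {
  stopifnot(n_nodes >= 2)
  L <- as.integer(n_nodes * (n_nodes - 1L) / 2)
  matrix(stats::rbinom(L * cfg$population_size, 1L, cfg$init_density),
         nrow = L, ncol = cfg$population_size)
}

#' Uniform crossover of two genomes
#'
#' For each entry independently with probability `cfg$swap_probability`, the
#' two parents' values at that entry are exchanged; other entries are
#' inherited unchanged. Uses the current RNG state.
#'
#' @param parent_a,parent_b 0/1 genome vectors of equal length.
#' @param cfg An [evolution_config()].
#' @return List with `child_a` and `child_b`.
#' @export
crossover <- function(parent_a, parent_b, cfg) {
  if (length(parent_a) != length(parent_b))
    stop("parent genomes must have equal length")
  swap <- stats::runif(length(parent_a)) < cfg$swap_probability
  child_a <- parent_a; child_b <- parent_b
  child_a[swap] <- parent_b[swap]
  child_b[swap] <- parent_a[swap]
  list(child_a = child_a, child_b = child_b)
}

#' Bit-flip mutation of a genome
#'
#' Each entry is independently flipped (1 to 0 or vice versa) with
#' probability `cfg$flip_probability`. Uses the current RNG state.
#'
#' @param genome 0/1 vector.
#' @param cfg An [evolution_config()].
#' @return Mutated copy of the genome.
#' @export
mutate <- function(genome, cfg) {
  flip <- stats::runif(length(genome)) < cfg$flip_probability
  out <- genome
  out[flip] <- 1L - out[flip]
  out
}

as_objective_matrix <- function(objectives) {
  if (is.matrix(objectives)) {
    stopifnot(ncol(objectives) >= 2)
    return(cbind(F_c = objectives[, 1], F_e = objectives[, 2]))
  }
  if (is.data.frame(objectives))
    return(cbind(F_c = objectives$F_c, F_e = objectives$F_e))
  if (is.list(objectives))
    return(cbind(F_c = vapply(objectives, `[[`, numeric(1), "F_c"),
                 F_e = vapply(objectives, `[[`, numeric(1), "F_e")))
  stop("objectives must be a matrix, data frame or list of objective pairs")
}

#' Fast non-dominated sorting
#'
#' Partitions objective pairs into Pareto fronts: every member of front 1 is
#' non-dominated in the whole set, every member of front k is non-dominated
#' once fronts 1..k-1 are removed. Both objectives are minimized.
#'
#' @param objectives Matrix/data frame with columns `F_c`, `F_e`, or a list
#'   of objective pairs.
#' @return List of integer index vectors, one per front.
#' @export
fast_nondominated_sort <- function(objectives) {
  obj <- as_objective_matrix(objectives)
  n <- nrow(obj)
  if (n == 0) stop("objectives must be nonempty")
  fc <- unname(obj[, 1]); fe <- unname(obj[, 2])
  dom <- outer(fc, fc, "<=") & outer(fe, fe, "<=") &
    (outer(fc, fc, "<") | outer(fe, fe, "<"))
  ndom <- colSums(dom)
  alive <- rep(TRUE, n)
  fronts <- list()
  while (any(alive)) {
    f <- which(alive & ndom == 0)
    fronts[[length(fronts) + 1L]] <- f
    alive[f] <- FALSE
    ndom <- ndom - colSums(dom[f, , drop = FALSE])
    ndom[!alive] <- NA_integer_
    ndom[alive & is.na(ndom)] <- 0L # unreachable; defensive
  }
  fronts
}

#' NSGA-II crowding distance within one front
#'
#' Per objective the front is sorted; the boundary solutions receive
#' `+Inf` and interior solutions the neighbour gap normalized by the
#' objective's range, summed over objectives. Exact duplicates of an
#' objective pair add no diversity: occurrences beyond the first get
#' crowding 0.
#'
#' @param objectives Objectives of the front members (see
#'   [fast_nondominated_sort()] for accepted forms).
#' @return Numeric vector of nonnegative crowding distances (may be `Inf`).
#' @export
crowding_distance <- function(objectives) {
  obj <- as_objective_matrix(objectives)
  n <- nrow(obj)
  key <- paste(obj[, 1], obj[, 2])
  first <- !duplicated(key)
  u <- obj[first, , drop = FALSE]
  m <- nrow(u)
  cd_u <- rep(0, m)
  if (m <= 2) {
    cd_u[] <- Inf
  } else {
    for (k in 1:2) {
      v <- u[, k]
      o <- order(v, seq_len(m))
      cd_u[o[c(1, m)]] <- Inf
      rng <- v[o[m]] - v[o[1]]
      if (rng > 0) {
        interior <- o[2:(m - 1)]
        cd_u[interior] <- cd_u[interior] +
          (v[o[3:m]] - v[o[1:(m - 2)]]) / rng
      }
    }
  }
  out <- rep(0, n)
  out[first] <- cd_u
  out
}

#' Environmental selection (elitist truncation)
#'
#' Fills the next population front by front; the first front that does not
#' fit entirely is truncated by descending crowding distance (ties broken by
#' candidate order, deterministically).
#'
#' @param objectives Objectives of the candidate pool (parents + offspring).
#' @param population_size Number of survivors to select.
#' @return Integer vector of selected candidate indices
#'   (length `population_size`).
#' @export
environmental_selection <- function(objectives, population_size) {
  obj <- as_objective_matrix(objectives)
  if (nrow(obj) < population_size)
    stop("candidate pool is smaller than the population size")
  fronts <- fast_nondominated_sort(obj)
  sel <- integer(0)
  for (f in fronts) {
    if (length(sel) + length(f) <= population_size) {
      sel <- c(sel, f)
    } else {
      cd <- crowding_distance(obj[f, , drop = FALSE])
      keep <- order(-cd, seq_along(f))[seq_len(population_size - length(sel))]
      sel <- c(sel, f[keep])
    }
    if (length(sel) == population_size) break
  }
  sel
}

#' Stall/termination check for the evolutionary loop
#'
#' Termination triggers when the generation counter reaches
#' `cfg$max_generations`, or when for `cfg$stall_generations` consecutive
#' generations either (a) the fraction of population slots whose genome is
#' absent from the previous generation's multiset is below
#' `cfg$change_fraction_threshold`, or (b) the relative change of both
#' objective means is below `cfg$objective_delta_threshold`.
#'
#' @param history Data frame with one row per generation and columns
#'   `generation`, `turnover`, `mean_F_c`, `mean_F_e` (row for generation 0
#'   carries the initial population's means and `NA` turnover).
#' @param cfg An [evolution_config()].
#' @return Logical: stop now?
#' @export
check_termination <- function(history, cfg) {
  g <- nrow(history)
  if (g == 0) return(FALSE)
  if (history$generation[g] >= cfg$max_generations) return(TRUE)
  rows <- which(history$generation > 0)
  if (length(rows) < cfg$stall_generations) return(FALSE)
  eps <- .Machine$double.eps
  stalled <- vapply(rows, function(t) {
    turn_ok <- !is.na(history$turnover[t]) &&
      history$turnover[t] < cfg$change_fraction_threshold
    d_fc <- abs(history$mean_F_c[t] - history$mean_F_c[t - 1]) /
      max(abs(history$mean_F_c[t - 1]), eps)
    d_fe <- abs(history$mean_F_e[t] - history$mean_F_e[t - 1]) /
      max(abs(history$mean_F_e[t - 1]), eps)
    obj_ok <- d_fc < cfg$objective_delta_threshold &&
      d_fe < cfg$objective_delta_threshold
    turn_ok || obj_ok
  }, logical(1))
  tail_rows <- utils::tail(stalled, cfg$stall_generations)
  all(tail_rows)
}

# exact multiset hash of genome columns (weighted bit sums are exact in
# doubles for genome lengths used here; two independent projections)
genome_hash_keys <- function(genomes, w1, w2) {
  paste(drop(crossprod(genomes, w1)), drop(crossprod(genomes, w2)))
}

multiset_turnover <- function(new_keys, old_keys) {
  old_tab <- table(old_keys)
  new_tab <- table(new_keys)
  shared <- intersect(names(old_tab), names(new_tab))
  matched <- sum(pmin(old_tab[shared], new_tab[shared]))
  1 - matched / length(new_keys)
}

eval_genomes <- function(genomes, distvec, n, spec, batch_seed) {
  fc <- drop(crossprod(genomes, distvec))
  fe <- cpp_eval_genomes(genomes, n,
                         upper_tri_index(n)$i, upper_tri_index(n)$j,
                         model_code(spec), model_weight(spec),
                         spec$louvain_restarts, as.integer(batch_seed))
  cbind(F_c = fc, F_e = fe)
}

#' Run one evolutionary optimization of a trade-off model
#'
#' A customized NSGA-II over binary network genomes: per generation, the
#' current population produces `population_size` uniform-crossover offspring
#' from disjoint random parent pairs, plus `population_size` mutated copies
#' of those offspring; parents and the 2x offspring pool then pass through
#' elitist environmental selection. On termination the mutually
#' non-dominated set of the final population is returned.
#'
#' @param geom A [region_geometry()] supplying the wiring-cost distances.
#' @param spec A [tradeoff_model()].
#' @param cfg An [evolution_config()]; `cfg$seed` fixes the whole run.
#' @param run_id Identifier stored in the archive provenance.
#' @param verbose Print a per-generation progress line?
#' @return A `pareto_archive` (see [merge_runs()]).
#' @export
run_evolution <- function(geom, spec = tradeoff_model(),
                          cfg = evolution_config(), run_id = 1L,
                          verbose = FALSE) {
  n <- nrow(geom$coordinates)
  ut <- upper_tri_index(n)
  distvec <- geom$distance[upper.tri(geom$distance)]
  pop_n <- cfg$population_size
  n_pairs <- pop_n %/% 2L

  with_local_seed(cfg$seed, {
    w1 <- sample.int(2^30, ut$length, replace = TRUE)
    w2 <- sample.int(2^30, ut$length, replace = TRUE)
    pop <- initialize_population(cfg, n)
    obj <- eval_genomes(pop, distvec, n, spec, sample.int(2^31 - 1L, 1L))
    history <- data.frame(generation = 0L, turnover = NA_real_,
                          mean_F_c = mean(obj[, 1]), mean_F_e = mean(obj[, 2]))
    gen <- 0L
    repeat {
      gen <- gen + 1L
      # disjoint random parent pairs -> uniform crossover offspring
      perm <- sample.int(pop_n)
      pa <- pop[, perm[seq_len(n_pairs)], drop = FALSE]
      pb <- pop[, perm[n_pairs + seq_len(n_pairs)], drop = FALSE]
      swap <- matrix(stats::runif(ut$length * n_pairs) < cfg$swap_probability,
                     nrow = ut$length)
      ca <- pa; cb <- pb
      ca[swap] <- pb[swap]; cb[swap] <- pa[swap]
      offspring <- cbind(ca, cb)
      # mutated copies of the crossover offspring
      flip <- matrix(stats::runif(length(offspring)) < cfg$flip_probability,
                     nrow = ut$length)
      mutants <- offspring
      mutants[flip] <- 1L - mutants[flip]
      new_cols <- cbind(offspring, mutants)
      new_obj <- eval_genomes(new_cols, distvec, n, spec,
                              sample.int(2^31 - 1L, 1L))
      cand <- cbind(pop, new_cols)
      cand_obj <- rbind(obj, new_obj)
      sel <- environmental_selection(cand_obj, pop_n)
      old_keys <- genome_hash_keys(pop, w1, w2)
      pop <- cand[, sel, drop = FALSE]
      obj <- cand_obj[sel, , drop = FALSE]
      turnover <- multiset_turnover(genome_hash_keys(pop, w1, w2), old_keys)
      history <- rbind(history,
                       data.frame(generation = gen, turnover = turnover,
                                  mean_F_c = mean(obj[, 1]),
                                  mean_F_e = mean(obj[, 2])))
      if (verbose) {
        f1 <- length(fast_nondominated_sort(obj)[[1]])
        message(sprintf(
          "run %d gen %d: front1 %d, mean F_c %.1f, mean F_e %.4f, turnover %.3f",
          run_id, gen, f1, mean(obj[, 1]), mean(obj[, 2]), turnover))
      }
      if (check_termination(history, cfg)) break
    }
    front1 <- fast_nondominated_sort(obj)[[1]]
    genomes <- pop[, front1, drop = FALSE]
    front_obj <- obj[front1, , drop = FALSE]
    keep <- !duplicated(genome_hash_keys(genomes, w1, w2))
    new_pareto_archive(genomes[, keep, drop = FALSE],
                       front_obj[keep, , drop = FALSE],
                       n, spec, run_id = run_id, seed = cfg$seed,
                       node_labels = rownames(geom$coordinates),
                       history = history)
  })
}

new_pareto_archive <- function(genomes, obj, n_nodes, spec, run_id, seed,
                               node_labels = NULL, history = NULL) {
  objectives <- data.frame(F_c = obj[, 1], F_e = obj[, 2],
                           efficiency_index = 1 - obj[, 2],
                           run = rep_len(run_id, ncol(genomes)),
                           seed = rep_len(seed, ncol(genomes)))
  structure(list(genomes = genomes, objectives = objectives,
                 n_nodes = as.integer(n_nodes), model = spec,
                 node_labels = node_labels, history = history),
            class = "pareto_archive")
}

#' @export
print.pareto_archive <- function(x, ...) {
  cat(sprintf("pareto_archive (%s): %d networks over %d nodes, F_c %.1f-%.1f\n",
              x$model$name, ncol(x$genomes), x$n_nodes,
              min(x$objectives$F_c), max(x$objectives$F_c)))
  invisible(x)
}

#' Number of archive members
#' @param archive A `pareto_archive`.
#' @return Integer count.
#' @export
archive_size <- function(archive) ncol(archive$genomes)

#' Decode archive members into networks
#'
#' @param archive A `pareto_archive`.
#' @param which Indices of members to decode (default all).
#' @return List of [binary_network()] objects.
#' @export
archive_networks <- function(archive, which = seq_len(archive_size(archive))) {
  lapply(which, function(k)
    network_from_genome(archive$genomes[, k], archive$n_nodes,
                        archive$node_labels))
}

#' Run the full multi-run evolution protocol
#'
#' Runs [run_evolution()] `cfg$n_runs` times with per-run seeds derived from
#' the master seed and merges the resulting Pareto sets.
#'
#' @param geom A [region_geometry()].
#' @param spec A [tradeoff_model()].
#' @param cfg An [evolution_config()].
#' @param verbose Print progress?
#' @return Merged `pareto_archive`.
#' @export
evolve_tradeoff_model <- function(geom, spec = tradeoff_model(),
                                  cfg = evolution_config(), verbose = FALSE) {
  run_seeds <- with_local_seed(cfg$seed,
                               sample.int(2^31 - 1L, cfg$n_runs))
  archives <- lapply(seq_len(cfg$n_runs), function(r) {
    run_cfg <- cfg
    run_cfg$seed <- run_seeds[r]
    run_evolution(geom, spec, run_cfg, run_id = r, verbose = verbose)
  })
  merge_runs(archives)
}

#' Merge Pareto archives from independent runs
#'
#' Takes the union of members, removes duplicate genomes, and keeps the
#' mutually non-dominated subset.
#'
#' @param archives List of `pareto_archive` objects from the same model and
#'   geometry.
#' @return A merged `pareto_archive`.
#' @export
merge_runs <- function(archives) {
  if (length(archives) == 0) stop("no archives to merge")
  models <- vapply(archives, function(a) a$model$name, character(1))
  nn <- vapply(archives, function(a) a$n_nodes, integer(1))
  if (length(unique(models)) > 1L)
    stop("cannot merge archives from different trade-off models")
  if (length(unique(nn)) > 1L)
    stop("cannot merge archives with different node counts")
  genomes <- do.call(cbind, lapply(archives, function(a) a$genomes))
  objectives <- do.call(rbind, lapply(archives, function(a) a$objectives))
  keys <- apply(genomes, 2, paste, collapse = "")
  keep <- !duplicated(keys)
  genomes <- genomes[, keep, drop = FALSE]
  objectives <- objectives[keep, , drop = FALSE]
  front1 <- fast_nondominated_sort(objectives)[[1]]
  a1 <- archives[[1]]
  out <- new_pareto_archive(genomes[, front1, drop = FALSE],
                            as.matrix(objectives[front1, c("F_c", "F_e")]),
                            a1$n_nodes, a1$model,
                            run_id = objectives$run[front1],
                            seed = objectives$seed[front1],
                            node_labels = a1$node_labels)
  out
}
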