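test_that("population initialization matches the configured density", {
  cfg <- evolution_config(population_size = 200, init_density = 0.1, seed = 1)
  set.seed(1)
  pop <- initialize_population(cfg, 90)
  expect_equal(dim(pop), c(90 * 89 / 2, 200))
  expect_true(all(pop %in% c(0L, 1L)))
  expect_equal(mean(pop), 0.1, tolerance = 0.01)

  set.seed(2)
  zero <- initialize_population(evolution_config(population_size = 5,
                                                 init_density = 0), 10)
  expect_true(all(zero == 0))
})

test_that("uniform crossover swaps entries positionwise", {
  cfg <- evolution_config(swap_probability = 0.5)
  set.seed(3)
  a <- rbinom(100, 1, 0.5); b <- rbinom(100, 1, 0.5)
  ch <- crossover(a, a, cfg)
  expect_identical(ch$child_a, a)
  expect_identical(ch$child_b, a)

  ch1 <- crossover(a, b, evolution_config(swap_probability = 1))
  expect_identical(ch1$child_a, b)
  expect_identical(ch1$child_b, a)

  for (rep in 1:10) {
    ch <- crossover(a, b, cfg)
    expect_true(all(ch$child_a == a | ch$child_a == b))
    # swaps are symmetric: where child_a took b, child_b took a
    expect_true(all((ch$child_a + ch$child_b) == (a + b)))
  }
  expect_error(crossover(a, b[1:50], cfg), "equal length")
})

test_that("mutation flips entries at the configured rate", {
  g <- rbinom(500, 1, 0.3)
  expect_identical(mutate(g, evolution_config(flip_probability = 0)), g)
  expect_identical(mutate(g, evolution_config(flip_probability = 1)), 1L - g)
  set.seed(4)
  flips <- replicate(50, sum(mutate(g, evolution_config(flip_probability = 0.1)) != g))
  expect_equal(mean(flips), 50, tolerance = 0.1) # 0.1 * 500
})

test_that("fast non-dominated sorting matches hand cases and the brute-force oracle", {
  obj <- rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  fronts <- fast_nondominated_sort(obj)
  expect_equal(fronts, list(1L, c(2L, 3L), 4L))

  expect_equal(fast_nondominated_sort(rbind(c(3, 7))), list(1L))
  same <- rbind(c(2, 2), c(2, 2), c(2, 2))
  expect_equal(fast_nondominated_sort(same), list(1:3))
  expect_error(fast_nondominated_sort(matrix(numeric(0), 0, 2)), "nonempty")

  set.seed(10)
  for (rep in 1:100) {
    n <- sample(2:50, 1)
    obj <- cbind(sample(1:8, n, TRUE), sample(1:8, n, TRUE))
    expect_equal(fast_nondominated_sort(obj), oracle_fronts(obj))
  }
})

test_that("crowding distance follows the boundary and duplicate conventions", {
  expect_equal(crowding_distance(rbind(c(1, 2))), Inf)
  expect_equal(crowding_distance(rbind(c(1, 2), c(2, 1))), c(Inf, Inf))

  three <- rbind(c(0, 2), c(1, 1), c(2, 0))
  expect_equal(crowding_distance(three), c(Inf, 2, Inf))

  dup <- rbind(c(0, 3), c(1, 2), c(1, 2), c(3, 0))
  cd <- crowding_distance(dup)
  expect_equal(cd[3], 0)
  expect_true(is.finite(cd[2]) && cd[2] > 0)
  expect_equal(cd[c(1, 4)], c(Inf, Inf))
})

test_that("environmental selection is elitist and matches a brute-force reimplementation", {
  set.seed(12)
  obj <- cbind(runif(10), runif(10))
  expect_error(environmental_selection(obj, 20), "smaller")

  # a full single front of exactly the target size is returned whole
  front <- cbind(1:6, 6:1)
  expect_setequal(environmental_selection(front, 6), 1:6)

  # a candidate dominating all others always survives
  for (rep in 1:10) {
    obj <- cbind(runif(12, 1, 2), runif(12, 1, 2))
    obj[7, ] <- c(0.5, 0.5)
    expect_true(7 %in% environmental_selection(obj, 3))
  }

  brute_selection <- function(obj, N) {
    fronts <- oracle_fronts(obj)
    sel <- integer(0)
    for (f in fronts) {
      if (length(sel) + length(f) <= N) { sel <- c(sel, f); next }
      cd <- crowding_distance(obj[f, , drop = FALSE])
      sel <- c(sel, f[order(-cd, seq_along(f))][seq_len(N - length(sel))])
      break
    }
    sel
  }
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(5:30, 1)
    obj <- cbind(sample(1:6, n, TRUE), sample(1:6, n, TRUE))
    N <- sample(seq_len(n), 1)
    expect_identical(sort(environmental_selection(obj, N)),
                     sort(brute_selection(obj, N)))
  }
})

test_that("termination triggers on the generation cap and on stable streaks", {
  cfg <- evolution_config(max_generations = 2000, stall_generations = 20)
  hist_row <- function(gen, turn, fc, fe)
    data.frame(generation = gen, turnover = turn, mean_F_c = fc,
               mean_F_e = fe)
  h <- do.call(rbind, lapply(0:2000, function(g)
    hist_row(g, if (g == 0) NA else 0.5, 100 - g * 0.01, 0.5)))
  expect_true(check_termination(h, cfg))

  # 20 identical generations -> stop
  h2 <- do.call(rbind, lapply(0:25, function(g)
    hist_row(g, if (g == 0) NA else 0, 100, 0.5)))
  expect_true(check_termination(h2, cfg))

  # 19 stalled generations then a large change -> keep going
  h3 <- do.call(rbind, lapply(0:20, function(g)
    hist_row(g, if (g == 0) NA else if (g <= 19) 0 else 0.8,
             if (g <= 19) 100 else 150, 0.5)))
  expect_false(check_termination(h3, cfg))

  # not enough history yet
  h4 <- do.call(rbind, lapply(0:5, function(g)
    hist_row(g, if (g == 0) NA else 0, 100, 0.5)))
  expect_false(check_termination(h4, cfg))
})

test_that("a toy evolution run returns a deterministic, mutually non-dominated archive", {
  geom <- toy_geometry(10, seed = 21)
  cfg <- evolution_config(population_size = 20, max_generations = 50,
                          seed = 77)
  arc <- run_evolution(geom, tradeoff_model("dual"), cfg)
  expect_s3_class(arc, "pareto_archive")
  expect_length(fast_nondominated_sort(arc$objectives), 1)

  arc2 <- run_evolution(geom, tradeoff_model("dual"), cfg)
  expect_identical(arc$genomes, arc2$genomes)
  expect_equal(arc$objectives, arc2$objectives)

  # elitism: the final front is never dominated by the initial population
  ut <- tradeoffnet:::upper_tri_index(10)
  distvec <- geom$distance[upper.tri(geom$distance)]
  init_obj <- local({
    set.seed(cfg$seed)
    w1 <- sample.int(2^30, ut$length, replace = TRUE) # consume as in the run
    w2 <- sample.int(2^30, ut$length, replace = TRUE)
    pop <- initialize_population(cfg, 10)
    fc <- drop(crossprod(pop, distvec))
    fe <- apply(pop, 2, function(g) {
      nt <- network_from_genome(g, 10)
      efficiency_objective(nt, tradeoff_model("dual"))
    })
    cbind(fc, fe)
  })
  for (k in seq_len(archive_size(arc))) {
    a <- c(arc$objectives$F_c[k], arc$objectives$F_e[k])
    dominated <- any(apply(init_obj, 1, function(b) oracle_dominates(b, a)))
    expect_false(dominated)
  }

  # population size is maintained every generation (history rows exist)
  expect_true(all(diff(arc$history$generation) == 1))
})

test_that("termination fires right after the stall window under constant objectives", {
  # saturated initialization with no mutation: every genome stays complete,
  # both objectives are constant, so the stall rule stops the run at
  # exactly stall_generations
  geom <- toy_geometry(8, seed = 31)
  cfg <- evolution_config(population_size = 16, max_generations = 500,
                          init_density = 1, flip_probability = 0,
                          stall_generations = 5, seed = 9)
  arc <- run_evolution(geom, tradeoff_model("dual"), cfg)
  expect_equal(max(arc$history$generation), 5)
})

test_that("merging runs filters to the non-dominated union", {
  geom <- toy_geometry(8, seed = 40)
  cfg1 <- evolution_config(population_size = 12, max_generations = 20,
                           seed = 1)
  cfg2 <- evolution_config(population_size = 12, max_generations = 20,
                           seed = 2)
  a1 <- run_evolution(geom, tradeoff_model("dual"), cfg1, run_id = 1)
  a2 <- run_evolution(geom, tradeoff_model("dual"), cfg2, run_id = 2)

  self_merge <- merge_runs(list(a1, a1))
  expect_equal(sort(self_merge$objectives$F_c), sort(a1$objectives$F_c))

  m <- merge_runs(list(a1, a2))
  expect_length(fast_nondominated_sort(m$objectives), 1)
  # equals the brute-force non-dominated filter of the deduplicated union
  union_obj <- rbind(as.matrix(a1$objectives[, c("F_c", "F_e")]),
                     as.matrix(a2$objectives[, c("F_c", "F_e")]))
  union_gen <- cbind(a1$genomes, a2$genomes)
  keys <- apply(union_gen, 2, paste, collapse = "")
  keep <- !duplicated(keys)
  expected <- oracle_fronts(union_obj[keep, , drop = FALSE])[[1]]
  expect_setequal(round(m$objectives$F_c, 9),
                  round(union_obj[keep, 1][expected], 9))

  a3 <- run_evolution(geom, tradeoff_model("tri_eloc"), cfg1)
  expect_error(merge_runs(list(a1, a3)), "different trade-off models")
})

test_that("evolve_tradeoff_model reproduces bit-identically under a fixed master seed", {
  geom <- toy_geometry(8, seed = 50)
  cfg <- evolution_config(population_size = 10, max_generations = 10,
                          n_runs = 2, seed = 123)
  m1 <- evolve_tradeoff_model(geom, tradeoff_model("dual"), cfg)
  m2 <- evolve_tradeoff_model(geom, tradeoff_model("dual"), cfg)
  expect_identical(m1$genomes, m2$genomes)
})
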