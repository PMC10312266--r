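test_that("recovery rate matches hand counts and boundary cases", {
  set.seed(60)
  emp <- random_network(8, 0.4)
  expect_equal(recovery_rate(emp, emp)$R, 1)
  comp <- binary_network(1 - diag(8) - emp$adjacency)
  rr <- recovery_rate(comp, emp)
  expect_equal(c(rr$R, rr$R0, rr$R1), c(0, 0, 0))

  # 4 nodes a,b,c,d: empirical {ab, bc, cd}, synthetic {ab, bd}
  emp4 <- binary_network(rbind(c(0, 1, 0, 0), c(1, 0, 1, 0),
                               c(0, 1, 0, 1), c(0, 0, 1, 0)))
  syn4 <- binary_network(rbind(c(0, 1, 0, 0), c(1, 0, 0, 1),
                               c(0, 0, 0, 0), c(0, 1, 0, 0)))
  rr4 <- recovery_rate(syn4, emp4)
  expect_equal(rr4$R1, 1 / 3)
  expect_equal(rr4$R0, 2 / 3)
  expect_equal(rr4$R, sqrt(2 / 9))
  expect_equal(recovery_rate(syn4, emp4, combine = "product")$R, 2 / 9)
  expect_equal(recovery_rate(syn4, emp4, combine = "mean")$R, 1 / 2)

  expect_error(recovery_rate(syn4, complete_net(4)), "both edges and")
  expect_error(recovery_rate(syn4, complete_net(5)), "same node count")
})

test_that("recovery rate is invariant to simultaneous node reordering and books entries exactly", {
  set.seed(61)
  for (rep in 1:10) {
    emp <- random_network(9, 0.35)
    syn <- random_network(9, 0.35)
    if (n_edges(emp) == 0 || n_edges(emp) == 36) next
    rr <- recovery_rate(syn, emp)
    o <- oracle_recovery(syn$adjacency, emp$adjacency)
    expect_equal(rr$R0, o$R0); expect_equal(rr$R1, o$R1)
    perm <- sample(9)
    rrp <- recovery_rate(binary_network(syn$adjacency[perm, perm]),
                         binary_network(emp$adjacency[perm, perm]))
    expect_equal(rrp$R, rr$R)
    # matched 1s + mismatched 0s = synthetic edge count
    matched1 <- rr$R1 * rr$n_ones
    mismatched0 <- (1 - rr$R0) * rr$n_zeros
    expect_equal(matched1 + mismatched0, n_edges(syn))
  }
})

test_that("distance-binned recovery respects bin boundaries and missing-bin rules", {
  # two clusters: within-pair distances < 20, across ~ 30
  coords <- rbind(c(0, 0, 0), c(5, 0, 0), c(30, 0, 0), c(35, 0, 0))
  geom <- region_geometry(coords)
  emp <- binary_network(rbind(c(0, 1, 1, 0), c(1, 0, 0, 0),
                              c(1, 0, 0, 1), c(0, 0, 1, 0)))
  syn <- binary_network(rbind(c(0, 1, 0, 0), c(1, 0, 0, 1),
                              c(0, 0, 0, 1), c(0, 1, 1, 0)))
  rep0 <- distance_binned_recovery(syn, emp, geom,
                                   bin_edges = c(0, 20, 40))
  # bin 1 (0-20mm): pairs 1-2 (d=5) and 3-4 (d=5): both empirical edges
  # -> no empirical 0s -> missing
  expect_true(is.na(rep0$per_bin_R[1]))
  # bin 2 (20-40mm): pairs 1-3 (30), 1-4 (35), 2-3 (25), 2-4 (30):
  # empirical 1s: {1-3}; synthetic has 1-3? no -> R1 = 0
  expect_equal(rep0$per_bin_R1[2], 0)
  # empirical 0s in bin 2: 1-4, 2-3, 2-4; synthetic realizes only 2-4
  expect_equal(rep0$per_bin_R0[2], 2 / 3)
  expect_equal(rep0$per_bin_n, c(2, 4))

  # one-bin geometry: the bin's R equals the overall R
  geom1 <- region_geometry(rbind(c(0, 0, 0), c(5, 0, 0), c(9, 0, 0),
                                 c(3, 4, 0)))
  set.seed(62)
  emp1 <- random_network(4, 0.5); syn1 <- random_network(4, 0.5)
  if (n_edges(emp1) > 0 && n_edges(emp1) < 6) {
    r_all <- recovery_rate(syn1, emp1)$R
    rep1 <- distance_binned_recovery(syn1, emp1, geom1,
                                     bin_edges = c(0, 20))
    expect_equal(rep1$per_bin_R[1], r_all)
  }

  # pairs beyond the last edge go to a flagged overflow bin
  far <- region_geometry(rbind(c(0, 0, 0), c(5, 0, 0), c(30, 0, 0),
                               c(300, 0, 0)))
  expect_warning(rep2 <- distance_binned_recovery(syn, emp, far,
                                                  bin_edges = c(0, 20, 40)),
                 "exceed")
  expect_equal(unname(rep2$overflow["n"]), 3)
})

test_that("bin AUC reproduces trapezoid arithmetic on the standard bins", {
  fake_report <- function(r) structure(list(bin_edges = seq(0, 120, 20),
                                            per_bin_R = r),
                                       class = "distance_bin_report")
  r <- c(0.9, 0.8, 0.4, 0.3, 0.2, 0.1)
  expect_equal(bin_auc(fake_report(r), min_distance = 40),
               (0.35 + 0.25 + 0.15) * 20)
  expect_equal(bin_auc(fake_report(rep(0.5, 6)), 40), 0.5 * 60)
  expect_equal(bin_auc(fake_report(rep(0, 6)), 40), 0)
  expect_equal(bin_auc(fake_report(r), 40, method = "rectangle"),
               sum(c(0.4, 0.3, 0.2, 0.1) * 20))
  expect_error(bin_auc(fake_report(c(0.9, 0.8, NA, 0.3, 0.2, 0.1)), 40),
               "missing")
})

test_that("cost-range filtering keeps inclusive endpoints", {
  geom <- toy_geometry(8, seed = 70)
  arc <- run_evolution(geom, tradeoff_model("dual"),
                       evolution_config(population_size = 12,
                                        max_generations = 15, seed = 3))
  all_kept <- cost_range_filter(arc, -Inf, Inf)
  expect_equal(archive_size(all_kept), archive_size(arc))
  none <- cost_range_filter(arc, -2, -1)
  expect_equal(archive_size(none), 0)
  fc <- arc$objectives$F_c[1]
  exact <- cost_range_filter(arc, fc, fc)
  expect_true(fc %in% exact$objectives$F_c)
  expect_error(cost_range_filter(arc, 5, 1), "must not exceed")
})

test_that("topological dissimilarity is a z-scored distance to the empirical centroid", {
  set.seed(71)
  syn <- matrix(rnorm(40), 8, 5)
  emp <- matrix(rnorm(20, mean = 1), 4, 5)
  colnames(syn) <- colnames(emp) <- paste0("m", 1:5)
  rep <- topological_dissimilarity(syn, emp)
  expect_length(rep$per_network_distance, 8)
  expect_true(all(rep$per_network_distance >= 0))

  # pooled z-scores have mean 0 / sd 1 per metric
  pool <- rbind(syn, emp)
  z <- scale(pool, center = rep$normalization$mean,
             scale = rep$normalization$sd)
  expect_equal(unname(colMeans(z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 5), tolerance = 1e-12)

  # a synthetic network equal to the raw empirical centroid-profile scores 0
  # distance only if its z-profile equals the centroid; construct directly:
  centroid_raw <- rep$normalization$mean +
    rep$empirical_centroid * rep$normalization$sd
  syn2 <- rbind(syn, centroid_raw)
  rep2 <- topological_dissimilarity(syn2, emp)
  # recompute: pooling changed, so check via its own normalization
  z9 <- (syn2[9, ] - rep2$normalization$mean) / rep2$normalization$sd
  expect_equal(rep2$per_network_distance[9],
               sqrt(sum((z9 - rep2$empirical_centroid)^2)))

  # increasing one network's deviation in one metric increases its distance
  syn3 <- syn
  syn3[1, 2] <- syn3[1, 2] + 5 * sign(syn3[1, 2] - mean(emp[, 2]) + 1e-9)
  rep3 <- topological_dissimilarity(syn3, emp)
  expect_gt(rep3$per_network_distance[1], rep$per_network_distance[1])

  # affine rescaling of a raw metric changes nothing
  syn4 <- syn; emp4 <- emp
  syn4[, 3] <- 10 * syn4[, 3] + 7; emp4[, 3] <- 10 * emp4[, 3] + 7
  rep4 <- topological_dissimilarity(syn4, emp4)
  expect_equal(rep4$per_network_distance, rep$per_network_distance)

  # zero-spread metrics are excluded and flagged
  syn5 <- syn; emp5 <- emp
  syn5[, 4] <- 1; emp5[, 4] <- 1
  rep5 <- topological_dissimilarity(syn5, emp5)
  expect_identical(rep5$excluded_metrics, "m4")
})
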