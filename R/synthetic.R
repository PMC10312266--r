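#' Configuration for the synthetic cohort generator
#'
#' Describes a pseudo-empirical cohort of subject-level binary connectomes
#' with distance-dependent, modular, hub-weighted connectivity, a
#' group-level consensus network, and behavior covariates (quadratic age
#' trajectories of cost/efficiency, an age-anticorrelated fluid-intelligence
#' score). Defaults emulate the empirical regime the analyses assume:
#' group density about 0.10-0.12 and group modularity about 0.5-0.65.
#'
#' @param n_regions Even region count (default 90).
#' @param n_subjects Cohort size (default 50).
#' @param n_modules Number of planted modules (default 5).
#' @param distance_scale Exponential decay constant of connection probability
#'   with centroid distance, mm (default 30).
#' @param within_module_boost Probability multiplier for same-module pairs
#'   (default 4).
#' @param target_density Expected subject network density (default 0.11).
#' @param hub_fraction Fraction of regions designated hubs (default 0.1).
#' @param hub_boost Probability multiplier for pairs touching a hub
#'   (default 2).
#' @param group_threshold Consensus threshold: an edge is kept if present in
#'   strictly more than this fraction of subjects (default 0.5).
#' @param age_range Age span in years (default 18-88).
#' @param noise_sd Score noise standard deviation, score units (default 6,
#'   which puts the age-score correlation near -0.65).
#' @param subject_noise Fraction of node pairs whose edge indicator is
#'   resampled independently per subject instead of following the shared
#'   cohort wiring diagram (default 0.3); keeps subject marginals exact
#'   while giving the cohort a consistent backbone.
#' @param age_density_amplitude Amplitude of the zero-mean quadratic
#'   age-density multiplier (default 0.35); produces inverted-U cost and
#'   efficiency trajectories.
#' @param sex_density_effect Multiplicative density shift for male subjects
#'   (default 0 = null-calibrated; set positive to plant a sex effect).
#' @param region_scatter_sd Standard deviation (mm) of region centroid
#'   scatter around module centers (default 10; values are truncated at
#'   1.5 sd so the overall distance span stays realistic).
#' @param homotopic_boost Probability multiplier for mirrored
#'   (inter-hemispheric homotopic) region pairs (default 25); emulates the
#'   strong callosal connectivity of real connectomes, which keeps costly
#'   long-range connections in the cohort networks.
#' @param seed Integer seed.
#' @return A `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(n_regions = 90L, n_subjects = 50L,
                                    n_modules = 5L, distance_scale = 30,
                                    within_module_boost = 4,
                                    target_density = 0.11,
                                    hub_fraction = 0.1, hub_boost = 2,
                                    group_threshold = 0.5,
                                    age_range = c(18, 88), noise_sd = 6,
                                    subject_noise = 0.3,
                                    age_density_amplitude = 0.35,
                                    sex_density_effect = 0,
                                    region_scatter_sd = 10,
                                    homotopic_boost = 25,
                                    seed = 1L) {
  stopifnot(n_regions >= 2 * n_modules, n_regions %% 2 == 0,
            n_subjects >= 1, n_modules >= 1,
            target_density > 0, target_density < 1,
            hub_fraction > 0, hub_fraction < 1,
            group_threshold > 0, group_threshold < 1,
            subject_noise >= 0, subject_noise <= 1,
            within_module_boost >= 1, hub_boost >= 1,
            length(age_range) == 2, age_range[1] < age_range[2])
  structure(list(n_regions = as.integer(n_regions),
                 n_subjects = as.integer(n_subjects),
                 n_modules = as.integer(n_modules),
                 distance_scale = distance_scale,
                 within_module_boost = within_module_boost,
                 target_density = target_density,
                 hub_fraction = hub_fraction, hub_boost = hub_boost,
                 group_threshold = group_threshold,
                 age_range = as.numeric(age_range), noise_sd = noise_sd,
                 subject_noise = subject_noise,
                 age_density_amplitude = age_density_amplitude,
                 sex_density_effect = sex_density_effect,
                 region_scatter_sd = region_scatter_sd,
                 homotopic_boost = homotopic_boost,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

# half-ellipsoid semi-axes (mm); sized so pairwise distances span ~5-120 mm
ellipsoid_axes <- c(x = 48, y = 52, z = 38)

# minimum distance (mm) between module centers; keeps modules spatially
# separable so the planted partition is recoverable
module_center_min_sep <- 55

# minimum |x| (mm) of lateral module centers; separates mirrored modules
# across the midline and sets the length scale of homotopic connections
hemisphere_min_x <- 24

sample_in_half_ellipsoid <- function(axes, min_x = 8) {
  repeat {
    p <- stats::runif(3, -1, 1) * axes
    if (sum((p / axes)^2) <= 1 && p[1] <= -min_x) return(p)
  }
}

#' Generate a mirrored two-hemisphere region geometry
#'
#' Modules are bilateral, as in real connectomes: each module has a pair of
#' mirrored centers, one per half-ellipsoid ("hemisphere"), and its regions
#' come in mirrored left/right pairs (equal |x|) scattered around those
#' centers. Pairwise distances span roughly 5-120 mm at the default scale.
#' A fixed fraction of regions is designated as hubs.
#'
#' @param cfg A [synthetic_cohort_config()].
#' @return List with `geometry` ([region_geometry()]), `module_truth`
#'   (named integer vector) and `hubs` (integer region indices).
#' @export
generate_geometry <- function(cfg) {
  n <- cfg$n_regions
  nm <- cfg$n_modules
  n_pairs <- n %/% 2L
  with_local_seed(cfg$seed, {
    # left-hemisphere module centers with rejection for minimum separation;
    # the right-hemisphere center of each module is the mirror image
    centers <- matrix(0, nm, 3)
    for (g in seq_len(nm)) {
      for (try in 1:500) {
        p <- sample_in_half_ellipsoid(ellipsoid_axes,
                                      min_x = hemisphere_min_x)
        if (g == 1 ||
            min(sqrt(rowSums(sweep(centers[seq_len(g - 1), , drop = FALSE],
                                   2, p)^2))) >= module_center_min_sep) break
      }
      centers[g, ] <- p
    }
    module_of_pair <- rep(seq_len(nm), length.out = n_pairs)
    coords <- matrix(0, n, 3)
    module_truth <- integer(n)
    ssd <- cfg$region_scatter_sd
    scatter <- function(k)
      pmax(pmin(stats::rnorm(k, sd = ssd), 1.5 * ssd), -1.5 * ssd)
    for (p in seq_len(n_pairs)) {
      g <- module_of_pair[p]
      left <- centers[g, ] + scatter(3)
      left[1] <- min(left[1], -2)
      coords[p, ] <- left
      coords[n_pairs + p, ] <- c(-left[1], left[2], left[3])
      module_truth[p] <- g
      module_truth[n_pairs + p] <- g
    }
    labels <- c(paste0("L", seq_len(n_pairs)), paste0("R", seq_len(n_pairs)))
    names(module_truth) <- labels
    hubs <- sort(sample.int(n, max(1L, floor(cfg$hub_fraction * n))))
    list(geometry = region_geometry(coords, labels),
         module_truth = module_truth, hubs = hubs)
  })
}

# distance/module/hub/homotopy connection weights on the upper triangle
connection_weights <- function(geom, module_truth, hubs, cfg) {
  ut <- upper.tri(geom$distance)
  d <- geom$distance[ut]
  n <- nrow(geom$distance)
  same <- outer(module_truth, module_truth, "==")[ut]
  is_hub <- seq_len(n) %in% hubs
  hub_pair <- outer(is_hub, is_hub, "|")[ut]
  pair_id <- matrix(0L, n, n)
  half <- n %/% 2L
  pair_id[cbind(seq_len(half), half + seq_len(half))] <- 1L
  homotopic <- (pair_id + t(pair_id))[ut] > 0L
  boost <- if (is.null(cfg$homotopic_boost)) 1 else cfg$homotopic_boost
  exp(-d / cfg$distance_scale) *
    cfg$within_module_boost^same * cfg$hub_boost^hub_pair *
    boost^homotopic
}

# solve for the proportionality constant so E[min(1, c*w)] = density
calibrate_edge_probabilities <- function(w, density) {
  f <- function(logc) mean(pmin(1, exp(logc) * w)) - density
  if (f(25) < 0)
    stop("cannot reach the target density with probabilities <= 1")
  c_star <- exp(stats::uniroot(f, c(-25, 25), tol = 1e-12)$root)
  pmin(1, c_star * w)
}

#' Generate one subject-level network
#'
#' Edge probability is proportional to
#' `exp(-d/distance_scale) * within_module_boost^[same module] *
#' hub_boost^[either endpoint is a hub]`, with the proportionality constant
#' calibrated so the expected density equals `cfg$target_density` (times
#' `density_multiplier`). Entries are drawn independently.
#'
#' @param geom A [region_geometry()].
#' @param module_truth Named integer module map from [generate_geometry()].
#' @param cfg A [synthetic_cohort_config()].
#' @param subject_seed Integer seed for this subject's draw.
#' @param hubs Hub region indices (default: from the cfg seed, as in
#'   [generate_geometry()]).
#' @param density_multiplier Optional multiplier on the target density.
#' @return A [binary_network()].
#' @export
generate_subject_network <- function(geom, module_truth, cfg,
                                     subject_seed = cfg$seed,
                                     hubs = integer(0),
                                     density_multiplier = 1) {
  w <- connection_weights(geom, module_truth, hubs, cfg)
  p <- calibrate_edge_probabilities(w, cfg$target_density * density_multiplier)
  genome <- with_local_seed(subject_seed,
                            as.integer(stats::runif(length(p)) < p))
  network_from_genome(genome, nrow(geom$distance), geom$labels)
}

#' Group-level consensus network
#'
#' Keeps an edge iff it is present in strictly more than `threshold` of the
#' subject networks (the "more than 50%" rule at the default threshold).
#'
#' @param subjects Nonempty list of [binary_network()] objects over a common
#'   node set.
#' @param threshold Fraction in (0, 1); strict inequality.
#' @return A [binary_network()].
#' @export
group_threshold_network <- function(subjects, threshold = 0.5) {
  if (length(subjects) == 0) stop("empty subject list")
  n <- n_nodes(subjects[[1]])
  if (!all(vapply(subjects, n_nodes, integer(1)) == n))
    stop("subjects must share a common node set")
  acc <- Reduce(`+`, lapply(subjects, function(s) s$adjacency))
  binary_network((acc / length(subjects) > threshold) * 1L,
                 subjects[[1]]$node_labels)
}

# zero-mean quadratic age modulation of density: positive near mid-range,
# negative at the extremes, so cost/efficiency follow an inverted U.
age_density_multiplier <- function(ages, cfg) {
  mid <- mean(cfg$age_range)
  half <- diff(cfg$age_range) / 2
  x <- (ages - mid) / half
  1 + cfg$age_density_amplitude * (1 / 3 - x^2)
}

#' Generate behavior covariates and age-structured subject networks
#'
#' Ages are uniform over `cfg$age_range`; each subject's network is drawn
#' with an age-dependent density multiplier peaking mid-range (planting
#' inverted-U cost/efficiency trajectories), an optional male density shift,
#' and a shared cohort wiring diagram perturbed per subject (see
#' `subject_noise` in [synthetic_cohort_config()]). The fluid-intelligence
#' style score decreases linearly with age plus Gaussian noise.
#'
#' @param geom,module_truth,hubs Output of [generate_geometry()].
#' @param cfg A [synthetic_cohort_config()].
#' @return List with `behavior` (data frame: id, age, sex, cattell) and
#'   `networks` (list of [binary_network()]).
#' @export
generate_behavior <- function(geom, module_truth, hubs, cfg) {
  n_sub <- cfg$n_subjects
  L <- as.integer(nrow(geom$distance) * (nrow(geom$distance) - 1L) / 2)
  w <- connection_weights(geom, module_truth, hubs, cfg)
  with_local_seed(cfg$seed + 59999L, {
    ages <- stats::runif(n_sub, cfg$age_range[1], cfg$age_range[2])
    sexes <- sample(c("male", "female"), n_sub, replace = TRUE)
    score <- 44 - 0.25 * (ages - cfg$age_range[1]) +
      stats::rnorm(n_sub, sd = cfg$noise_sd)
    shared_u <- stats::runif(L) # cohort wiring diagram latent
    mult <- age_density_multiplier(ages, cfg) *
      ifelse(sexes == "male", 1 + cfg$sex_density_effect, 1)
    networks <- lapply(seq_len(n_sub), function(s) {
      p <- calibrate_edge_probabilities(w, cfg$target_density * mult[s])
      resample <- stats::runif(L) < cfg$subject_noise
      u <- shared_u
      u[resample] <- stats::runif(sum(resample))
      network_from_genome(as.integer(u < p), nrow(geom$distance),
                          geom$labels)
    })
    list(behavior = data.frame(id = sprintf("sub%03d", seq_len(n_sub)),
                               age = ages, sex = sexes, cattell = score,
                               stringsAsFactors = FALSE),
         networks = networks)
  })
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper producing geometry, truth partition, hub set,
#' age-structured subject networks, behavior table and the group-level
#' consensus network in one seeded call.
#'
#' @param cfg A [synthetic_cohort_config()].
#' @return A `subject_network_set` list with elements `geometry`,
#'   `module_truth`, `hubs`, `networks`, `behavior`, `group_network` and
#'   `config`.
#' @export
generate_cohort <- function(cfg = synthetic_cohort_config()) {
  geo <- generate_geometry(cfg)
  beh <- generate_behavior(geo$geometry, geo$module_truth, geo$hubs, cfg)
  group <- group_threshold_network(beh$networks, cfg$group_threshold)
  structure(list(geometry = geo$geometry, module_truth = geo$module_truth,
                 hubs = geo$hubs, networks = beh$networks,
                 behavior = beh$behavior, group_network = group,
                 config = cfg),
            class = "subject_network_set")
}

#' @export
print.subject_network_set <- function(x, ...) {
  n <- length(x$networks)
  dens <- mean(vapply(x$networks, function(s)
    n_edges(s) / choose(n_nodes(s), 2), numeric(1)))
  cat(sprintf(
    "subject_network_set: %d subjects x %d regions, mean density %.3f\n",
    n, n_nodes(x$group_network), dens))
  invisible(x)
}

#' Degree-preserving random benchmark networks
#'
#' Random benchmark ensemble for the recovery-rate comparison: rewires the
#' empirical network while preserving its exact degree sequence.
#'
#' @param empirical A [binary_network()].
#' @param cfg A [null_ensemble_config()] (default: 100 networks).
#' @return List of [binary_network()] objects.
#' @export
generate_random_benchmarks <- function(empirical,
                                       cfg = null_ensemble_config()) {
  degree_preserving_rewire(empirical, cfg)
}
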