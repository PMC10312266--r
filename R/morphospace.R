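#' Map networks into the trade-off morphospace
#'
#' Each network becomes a point `(F_c, 1 - F_e)` in the morphospace of the
#' given model, plus the slope `(1 - F_e) / F_c` summarizing its relative
#' trade-off between cost and communication efficiency. Networks with zero
#' cost (edgeless) get a flagged `NA` slope and should be excluded from
#' slope analyses.
#'
#' @param nets List of [binary_network()] objects.
#' @param geom A [region_geometry()].
#' @param spec A [tradeoff_model()].
#' @return Data frame with columns `F_c`, `efficiency_index`, `slope` and
#'   `flagged`.
#' @export
map_to_morphospace <- function(nets, geom, spec = tradeoff_model()) {
  rows <- lapply(nets, function(nt) {
    op <- evaluate_network(nt, geom, spec)
    slope <- if (op$F_c > 0) op$efficiency_index / op$F_c else NA_real_
    data.frame(F_c = op$F_c, efficiency_index = op$efficiency_index,
               slope = slope, flagged = op$F_c <= 0)
  })
  do.call(rbind, rows)
}

#' Quadratic age fit of a morphospace index
#'
#' Least-squares fit of `index = b0 + b1 * age + b2 * age^2`. The sign of
#' `b2` distinguishes U-shaped (`b2 > 0`) from inverted-U (`b2 < 0`)
#' trajectories.
#'
#' @param index_values Numeric vector of index values.
#' @param ages Numeric vector of ages in years.
#' @return List with `r_squared`, `coefficients` (`b0`, `b1`, `b2`) and the
#'   fitted `model`.
#' @export
quadratic_age_fit <- function(index_values, ages) {
  if (length(index_values) != length(ages)) stop("length mismatch")
  ok <- stats::complete.cases(index_values, ages)
  index_values <- index_values[ok]; ages <- ages[ok]
  if (length(ages) < 4) stop("need at least 4 subjects")
  if (stats::sd(ages) == 0) stop("age variance must be positive")
  fit <- stats::lm(index_values ~ ages + I(ages^2))
  if (any(is.na(stats::coef(fit)))) stop("degenerate design: fit failed")
  co <- unname(stats::coef(fit))
  list(r_squared = summary(fit)$r.squared,
       coefficients = c(b0 = co[1], b1 = co[2], b2 = co[3]),
       model = fit)
}

#' One-sided permutation p-value with add-one correction
#'
#' `p = (1 + #(null >= observed)) / (1 + n_permutations)` in the one-sided
#' mode (the fraction of the null distribution at or above the observed
#' statistic); the two-sided mode compares absolute values.
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of null statistics (or a generator
#'   function returning one null value per call).
#' @param n_permutations Number of permutations when `null_values` is a
#'   generator (default 10000).
#' @param sidedness `"greater"` (default, the literal one-sided rule) or
#'   `"two.sided"`.
#' @return An `association_result` list with `statistic`, `p_perm`,
#'   `n_permutations`, `null_mean`, `null_sd` and `sidedness`.
#' @export
permutation_test <- function(observed, null_values, n_permutations = 10000L,
                             sidedness = c("greater", "two.sided")) {
  sidedness <- match.arg(sidedness)
  if (is.function(null_values))
    null_values <- vapply(seq_len(n_permutations),
                          function(i) null_values(), numeric(1))
  n <- length(null_values)
  stopifnot(n >= 1)
  exceed <- if (sidedness == "greater") sum(null_values >= observed)
            else sum(abs(null_values) >= abs(observed))
  structure(list(statistic = observed,
                 p_perm = (1 + exceed) / (1 + n),
                 n_permutations = n,
                 null_mean = mean(null_values),
                 null_sd = stats::sd(null_values),
                 sidedness = sidedness),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("statistic = %.4f, permutation p = %.4g (%s, %d permutations)\n",
              x$statistic, x$p_perm, x$sidedness, x$n_permutations))
  invisible(x)
}

#' Age-controlled sex difference of a morphospace index
#'
#' Residualizes the index on age (linear + quadratic by default), takes the
#' male-minus-female difference of residual means, and assesses significance
#' by permuting sex labels.
#'
#' @param index_values Numeric index vector.
#' @param ages Ages in years.
#' @param sexes Factor/character vector with levels including `"male"` and
#'   `"female"`.
#' @param n_permutations Label permutations (default 10000).
#' @param seed Integer seed.
#' @param age_control `"quadratic"` (default) or `"linear"`.
#' @param sidedness Passed to [permutation_test()].
#' @return An `association_result`.
#' @export
gender_difference_age_controlled <- function(index_values, ages, sexes,
                                             n_permutations = 10000L,
                                             seed = 1L,
                                             age_control = c("quadratic",
                                                             "linear"),
                                             sidedness = c("greater",
                                                           "two.sided")) {
  age_control <- match.arg(age_control)
  sidedness <- match.arg(sidedness)
  sexes <- as.character(sexes)
  if (!all(c("male", "female") %in% sexes))
    stop("both sexes must be represented")
  resid <- if (age_control == "quadratic")
    stats::residuals(stats::lm(index_values ~ ages + I(ages^2)))
  else stats::residuals(stats::lm(index_values ~ ages))
  is_male <- sexes == "male"
  stat_fun <- function(male_mask)
    mean(resid[male_mask]) - mean(resid[!male_mask])
  observed <- stat_fun(is_male)
  nulls <- with_local_seed(seed, {
    vapply(seq_len(n_permutations),
           function(i) stat_fun(sample(is_male)), numeric(1))
  })
  permutation_test(observed, nulls, sidedness = sidedness)
}

#' Pearson association with permutation significance
#'
#' Pearson correlation between a morphospace index and a behavioral score,
#' with the null distribution obtained by shuffling the score vector.
#'
#' @param index_values Numeric index vector.
#' @param scores Numeric score vector (e.g. Cattell totals).
#' @param n_permutations Number of shuffles (default 10000).
#' @param seed Integer seed.
#' @param sidedness Passed to [permutation_test()].
#' @return An `association_result` whose `statistic` is Pearson r.
#' @export
pearson_association <- function(index_values, scores,
                                n_permutations = 10000L, seed = 1L,
                                sidedness = c("greater", "two.sided")) {
  sidedness <- match.arg(sidedness)
  ok <- stats::complete.cases(index_values, scores)
  x <- index_values[ok]; y <- scores[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  observed <- stats::cor(x, y)
  # vectorized null: correlations of x with column-shuffled copies of y
  xs <- scale(x)[, 1]
  ys <- scale(y)[, 1]
  nulls <- with_local_seed(seed, {
    perm <- replicate(n_permutations, sample.int(length(y)))
    drop(crossprod(matrix(ys[perm], nrow = length(y)), xs)) / (length(y) - 1)
  })
  permutation_test(observed, nulls, sidedness = sidedness)
}

#' Read a tab-delimited behavior table
#'
#' Expected header columns: `id`, `age`, `sex`, `cattell` (extra covariate
#' columns are kept).
#'
#' @param path File path.
#' @return Data frame with validated `id` (unique) and positive `age`.
#' @export
read_behavior <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("id", "age", "sex", "cattell")
  if (!all(need %in% colnames(tab)))
    stop("behavior table must contain columns id, age, sex, cattell")
  if (anyDuplicated(tab$id)) stop("duplicate subject ids")
  if (any(tab$age <= 0)) stop("ages must be positive")
  tab
}
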