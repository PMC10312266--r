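---
title: "Cost-efficiency trade-off models of the structural connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-efficiency trade-off models of the structural connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tradeoffnet)
```

## The scientific question

Macroscale brain networks are thought to be shaped by a trade-off between
the material cost of wiring and the communication capability the wiring
buys. `tradeoffnet` implements this idea as a family of two-objective
optimization problems over binary networks on a fixed region geometry and
provides the full battery for comparing the resulting Pareto-optimal
synthetic networks with (stand-ins for) empirical connectomes.

Every network is a symmetric 0/1 adjacency matrix over N labelled regions
with centroid coordinates in mm. Two objectives are minimized jointly:

* **Wiring cost** `F_c = sum over connected pairs of d(i, j)`, the total
  Euclidean length of all connections (mm). It is the same in every model.
* **Efficiency objective** `F_e`, where smaller is better:
  * `dual`: `F_e = 1 - Eg` (integration only),
  * `tri_eloc`: `F_e = w_Eloc (1 - Eg) + (1 - w_Eloc)(1 - Eloc)`,
  * `tri_q`: `F_e = w_Q (1 - Eg) + (1 - w_Q)(1 - Q)`,

  with `Eg` the global efficiency (mean inverse shortest-path length over
  ordered pairs, unreachable pairs contributing 0), `Eloc` the mean nodal
  local efficiency, and `Q` the Newman-Girvan modularity of the best
  Louvain partition. The tri-factor models add a segregation term -- local
  clustering efficiency or modular structure -- to the classical
  cost-integration trade-off.

The default weights `w_Eloc = 0.9` and `w_Q = 0.8` are the settings
reported to recover empirical connectomes best; both live strictly inside
(0, 1) and are exposed in `tradeoff_model()`. As `w -> 1` both tri-factor
objectives converge to the dual objective (a property the test suite
checks numerically).

A network's position in the **morphospace** is `(F_c, 1 - F_e)`; the slope
`(1 - F_e)/F_c` (per mm) summarizes its relative trade-off. Networks with
`F_c = 0` have no defined slope and are flagged rather than silently
dropped.

## The optimizer

`run_evolution()` is a customized NSGA-II over genomes that are the strict
upper triangle of the adjacency matrix:

1. **Initialization**: `population_size` genomes (default 200) with each
   entry 1 independently with probability `init_density` (default 0.1).
2. **Crossover**: the population is split into disjoint random pairs; each
   pair produces two children by uniform crossover (each entry swapped
   between the parents with probability 0.5). This realizes "swap a random
   portion of entries" in its standard binary-genome form; the swap
   probability is configurable.
3. **Mutation**: each of the crossover offspring is copied and every entry
   of the copy flips with probability 0.1. Mutants are *added to* the
   offspring pool, so each generation evaluates `2 x population_size` new
   genomes. Applying mutation to offspring copies (rather than in place,
   or to parents) is a design choice; the rate and target are
   configurable.
4. **Selection**: parents and offspring compete in elitist environmental
   selection -- fast non-dominated sorting into Pareto fronts, then
   truncation of the first overflowing front by descending crowding
   distance. Crowding is computed on unique objective pairs; duplicate
   pairs beyond the first occurrence get crowding 0, since they add no
   diversity. Truncation ties break by candidate order, so selection is
   deterministic given the RNG stream.
5. **Termination**: after `max_generations` (default 2000), or when for
   `stall_generations` (default 20) consecutive generations either less
   than 5% of population slots hold a genome absent from the previous
   generation's multiset, or both objective means changed by less than
   0.1% in relative terms. "Individuals changed" is operationalized as
   multiset turnover because the source procedure does not pin down a
   definition; both thresholds are configurable.

A full experiment runs the algorithm `n_runs` times (default 30) with
per-run seeds derived from one master seed, merges the final populations'
non-dominated sets, deduplicates genomes and keeps the non-dominated
subset (`evolve_tradeoff_model()`, `merge_runs()`). Within the `tri_q`
objective, modularity is evaluated with a small seeded restart count
(default 5) during evolution for speed -- roughly 10^5 objective
evaluations per run -- while all reported metrics use the full 100-restart
policy. Degenerate (edgeless) genomes are legal during evolution and take
the worst efficiency value 1 instead of erroring, so the optimizer loop is
total.

Everything is reproducible bit-for-bit from the seeds: the R-level loop
draws from a locally seeded RNG (the caller's `.Random.seed` is restored),
and the compiled kernels use an own deterministic 64-bit generator seeded
from the R side.

## Graph metrics and null models

The nine-metric profile (`metric_vector()`) is `Cp, Lp, gamma, lambda,
sigma, Eg, Eloc, Q, Mn`. Numerical conventions, chosen where several
exist in common toolboxes:

* Unreachable pairs contribute 0 to `Eg` (the `1/Inf = 0` convention);
  `Lp` averages over reachable ordered pairs only, which keeps it finite
  on near-connected graphs. A stricter mode
  (`disconnected = "error"`) is available.
* Nodes of degree < 2 contribute 0 to `Cp` and to nodal local efficiency.
* `gamma`, `lambda`, `sigma = gamma/lambda` normalize `Cp` and `Lp` by the
  means of a degree-preserving null ensemble: Maslov-Sneppen double-edge
  swaps, 10 attempted swaps per edge, 100 nulls by default (20 in the
  scaled-down acceptance experiment). Degree sequences are preserved
  exactly, not just in distribution.
* `Q` and `Mn` come from the same best-of-restarts Louvain partition
  (default 100 restarts, seeded; ties keep the first-found partition).
  If every restart lands below the trivial one-module partition, that
  trivial partition (Q = 0) is returned, so reported Q is never negative.

The kernels (BFS over bit-packed adjacency rows, popcount triangle
counting, Louvain with explicit aggregation) are compiled; the test suite
pins them to brute-force R oracles (all-pairs BFS, explicit triangle
loops, exhaustive partition search up to Bell(7) partitions) and to igraph
on random graphs.

## Comparison battery

* `recovery_rate()`: `R1` = fraction of empirical edges reproduced, `R0` =
  fraction of empirical non-edges reproduced, combined as
  `R = sqrt(R0 * R1)` by default. The geometric mean is used because the
  printed formula in the source material is typographically ambiguous
  ("R = R0 R1") while its reported random-benchmark value (about 0.41 at
  density about 0.1) is consistent with the geometric mean and not with
  the raw product (about 0.18); `combine = "product"` and `"mean"` remain
  available.
* `distance_binned_recovery()`: the same rate restricted to node pairs in
  20 mm Euclidean distance bins spanning 0-120 mm (left-closed,
  right-open, last bin closed); bins with no empirical edges or no
  empirical non-edges are reported missing, not zero; pairs beyond the
  last edge land in a flagged overflow bin.
* `bin_auc()`: trapezoidal area of per-bin R over the bin midpoints at and
  beyond 40 mm (midpoints 50/70/90/110 mm). A rectangle-sum variant is
  available.
* `cost_range_filter()`: inclusive cost-interval filter used before every
  topological comparison, so cost differences do not masquerade as
  topology differences.
* `topological_dissimilarity()`: z-scores each metric over the pooled
  synthetic + empirical networks, averages the normalized empirical
  profiles into a centroid, and reports each synthetic network's Euclidean
  distance to it. Zero-spread metrics are excluded and flagged.

`select_representative()` picks the cost-filtered archive member with the
highest recovery rate (ties: lower cost, then lexicographic genome).
Partition agreement uses Cohen's kappa after greedy one-to-one
maximum-overlap label matching -- deterministic, and exact for
well-separated partitions. Attacks remove nodes either uniformly at
random (100 repetitions by default, mean and SD reported) or in descending
degree order (static ranking by default; an adaptive mode recomputes
degrees after each removal), tracking raw `Eg`/`Eloc` on the remaining
subgraph over removal fractions 0.1-0.9; `attack_auc()` integrates the raw
curves by trapezoid. Raw (unnormalized) preserved efficiency is used
because the magnitudes of the reference AUCs (about 0.2-0.3) match raw
efficiency values declining over the grid.

## Behavioral association

`quadratic_age_fit()` fits `index ~ b0 + b1 age + b2 age^2`; the sign of
`b2` distinguishes U from inverted-U trajectories. The sex contrast
residualizes the index on age and age squared (linear-only is available)
and permutes sex labels. Correlations with the behavior score permute the
score vector. All permutation p-values follow the literal one-sided rule
-- the fraction of the null at or above the observed value -- with an
add-one correction so p is never 0; a two-sided mode on magnitudes is
available and always reported explicitly in the result object.

## The synthetic cohort generator

`generate_cohort()` produces the pseudo-empirical data every pipeline
stage is tested against: a mirrored two-hemisphere geometry, subject-level
networks, a group consensus network (edge kept iff present in strictly
more than 50% of subjects) and a behavior table.

Geometry: modules are bilateral -- each of the 5 default modules has a
mirrored pair of centers, one per half-ellipsoid (semi-axes 48/52/38 mm,
lateral centers at |x| >= 24 mm, pairwise center separation >= 55 mm), and
regions come in mirrored left/right pairs scattered around the centers
(sd 10 mm, truncated at 1.5 sd). Bilateral modules were chosen after
observing that Louvain on any realistically homotopically-connected
network merges mirrored lobes into one community; a truth partition that
splits them hemispherically would therefore be unrecoverable in principle.
Pairwise distances span roughly 3-125 mm at the defaults.

Connectivity: the probability of an edge is proportional to
`exp(-d/30 mm)` times 4 for same-module pairs, times 2 for pairs touching
one of the 10% designated hub regions, times 25 for mirrored (homotopic)
pairs -- the latter emulating the strong, costly callosal connections of
real connectomes. The proportionality constant is solved numerically so
the expected density equals the target (0.11), with probabilities clamped
at 1 and an explicit error if the target is unreachable. Subjects share a
cohort-level wiring diagram: each subject resamples an independent 30% of
node pairs (`subject_noise`), which leaves every subject's marginal edge
law exactly as specified while giving the cohort the consistent backbone
that makes a >50% consensus network meaningful. Over 10 seeds at the
defaults the group network has density 0.09-0.12, Louvain modularity
0.43-0.52 with 5 modules, and the planted partition is recovered with
kappa >= 0.93.

Behavior: ages are uniform on 18-88 years; each subject's target density
is modulated by a zero-mean quadratic in age (amplitude 0.35) peaking
mid-range, which plants the inverted-U cost and efficiency trajectories;
the fluid-intelligence-style score decreases linearly with age with
Gaussian noise (sd 6, putting the age-score correlation near -0.65); a
male/female density shift is available and defaults to 0 so the sex
contrast is null-calibrated out of the box.

What the generator does *not* emulate: tractography artefacts
(distance-dependent false negatives, spurious short-range edges),
hemispheric asymmetries, heavy-tailed degree distributions beyond the
planted hubs, and any genuine coupling between topology and the behavior
score beyond the planted age pathway. Passing tests therefore demonstrate
that the pipeline's statistics behave correctly under a controlled data
model, not that the scientific conclusions transfer to any particular
empirical dataset.

## Problem sizes used by the tests

The acceptance experiment evolves 60-region networks with population 100
for up to 300 generations, 3 runs per model, merges the runs, filters to
the middle 50% of the surrogate cohort's cost range and normalizes
small-worldness against 20 degree-preserving nulls per network; these
sizes keep a full three-model experiment to a few minutes while leaving
every qualitative contrast (small-worldness above 1, each trained metric
highest under its own model) measurable. Oracle-equivalence checks use
graphs of up to 10 nodes and objective sets of up to 50 points, 100 random
instances each; permutation calibration uses 10,000 simulated null
datasets at 200 permutations each. One caveat discovered at this scale:
the reference dual-versus-tri_eloc gap in mean global efficiency is only
about 0.7%, which is below the sampling resolution of a 60-region
experiment with about 15 cost-filtered networks per model, so that single
ordering is not reliably reproduced at desk scale (the modularity and
local-efficiency orderings are, in every seed set tried).

## Known limitations

* Louvain is a heuristic; outside the exhaustively-checked tiny-graph
  regime the reported Q is a seeded best-of-restarts lower bound on the
  optimum.
* The evolutionary floor of the cost objective is set by the mutation
  pressure (a per-entry flip rate of 0.1 re-randomizes about 10% of a
  genome), so very sparse, very cheap networks are underexplored at small
  generation budgets; the cost filter keeps comparisons inside the
  well-covered region.
* Wiring cost uses straight-line centroid distances, a proxy that
  underestimates curved fiber lengths, particularly between hemispheres.
* The whole pipeline is specified for undirected binary networks;
  weighted or directed extensions are out of scope.
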