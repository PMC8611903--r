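---
title: "Geometric surrogate null models for spatially embedded brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric surrogate null models for spatially embedded brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geonull)
```

## The question the package answers

Structural connectomes are spatially embedded: connection weights fall off
steeply with the distance between regions, because long axonal pathways are
costly and because reconstruction methods (diffusion tractography in
particular) lose sensitivity with streamline length. Many celebrated
topological findings — modules, hubs, efficient small-world layouts — can
therefore be partly or wholly a consequence of geometry rather than of any
additional organisational principle.

`geonull` quantifies that confound. For a weighted symmetric connectome
with node coordinates, region volumes and a pairwise fiber-distance matrix,
it builds two null ensembles:

* **Geometric surrogates** (`W_geo`) preserve the empirical node-strength
  distribution *and* the low-order relationship between log-weight and
  fiber distance, destroying all other topology.
* **Random surrogates** (`W_rand`) preserve the strength distribution only.

Any network property that survives in `W_geo` is attributable to spatial
embedding plus the strength distribution; the ratio of an empirical metric
to its `W_geo` ensemble mean (e.g. `Q_emp / mean(Q_geo)`) measures the
structure *beyond* geometry, with 1 meaning complete geometric
determination.

## The surrogate construction

Weights are modelled on the natural-log scale. With `f_ij` the fiber
distance between regions `i` and `j`:

1. **Trend fit.** `log w_ij ~ g(f_ij)` with `g` a cubic polynomial, least
   squares over the positive upper-triangle edges ([fit_trend()]). A
   parabola `h(f)` is then fitted to the absolute residuals, capturing the
   heteroscedastic spread of log-weights around the trend.
2. **Detrend.** `r_ij = (log w_ij - g(f_ij)) / max(h(f_ij), floor)`. The
   residuals have essentially zero Spearman and Pearson correlation with
   distance.
3. **Shuffle.** The residuals are permuted uniformly at random over the
   positive upper-triangle positions and mirrored, erasing all structure
   the trend does not capture.
4. **Retrend.** The transformations are inverted
   (`log w = g + h·r`), reimposing the low-order distance dependence.
5. **Rank-map.** The surrogate values are replaced by the *original*
   weight multiset mapped through rank order, so the pre-restoration
   surrogate carries exactly the empirical weights, placed at
   geometry-respecting positions.
6. **Strength restoration.** Row/column sums are driven toward the
   empirical strengths by multiplicative symmetric scaling sweeps,
   `w_ij ← w_ij·sqrt((t_i/s_i)(t_j/s_j))`, which preserves symmetry and
   nonnegativity by construction (relative tolerance `1e-3`, at most 1000
   sweeps; non-convergence is flagged per surrogate, never hidden).

Random surrogates skip steps 1–5 and simply permute the weights before
restoration.

### Which strengths are restored

The strength targets can be matched two ways. `"nodewise"` drives every
node to its own empirical strength. That, however, makes surrogate
strength-hub sets *identical* to the empirical one — the null could never
relocate hubs, and hub-peripherality comparisons against it would be
vacuous. The default for surrogate construction is therefore
`"distribution"`: the sorted empirical strengths are assigned to nodes by
the rank of their own surrogate strength, so the strength *distribution*
is reproduced while the identity of the strong nodes remains the
geometry-driven outcome of the shuffle. This is also what makes the
random-surrogate weight field statistically flat against distance: with
node-wise targets, the positional information carried by the strengths
leaks back into the weights.

### Numerical choices

* The spread curve is floored at `max(1e-6 × median fitted spread, 1e-6)`
  log-units: dividing by a vanishing (or negative) parabola value is
  ill-defined, and for noiseless inputs the floor keeps detrended
  residuals at numerical zero.
* The parabola is fitted to *absolute* residuals. A fit to signed
  residuals would be a second mean curve, not a spread model, and dividing
  by it could flip signs.
* Natural logs throughout; the base cancels in the detrend/retrend round
  trip.
* Zero-weight pairs are excluded from fitting and shuffling and stay zero
  in surrogates (graphs in this regime are nearly fully connected, and
  their count is recorded on the trend model).
* Thresholding to an edge density keeps the `ceiling(d·N(N−1)/2)`
  heaviest pairs; ties break lexicographically by (row, column) so density
  sweeps are deterministic and nested.
* Hemispheric symmetry is enforced by *averaging* mirrored entries: the
  unique symmetric, idempotent, total-weight-conserving choice (summation
  is available as an option).
* Eigenvector centrality uses shifted power iteration (`W + µI`); the
  shift keeps the Perron eigenvalue strictly dominant in magnitude, which
  a bipartite positive support would otherwise break.
* Z-scoring of log-weights uses the population-SD convention, so a single
  bin containing all edges reports exactly SD 1; binned profile SDs use
  the same convention for consistency.
* Multiple comparisons across profile bins are Bonferroni-corrected by
  default (Benjamini–Hochberg available).

## Graph measures

Modularity (`Q`), Louvain optimization with restarts, participation
coefficients, eigenvector centrality, binary global/local efficiency,
clustering and path length follow their standard weighted/binary
definitions; the package computes the analysis-facing ones itself (each is
unit-tested against independent brute-force oracles on small graphs) and
uses igraph for Louvain and BFS distances. Three conventions worth
stating:

* *Local efficiency* of node `i` is the global efficiency of the subgraph
  induced on `i`'s neighbors (the Latora–Marchiori reading; nodes with
  fewer than two neighbors score 0).
* Disconnected pairs contribute 0 to efficiencies and are excluded from
  the characteristic path length (their count is reported alongside).
* Louvain runs at resolution 1 with 100 restarts for empirical graphs and
  10 per surrogate ensemble member (configurable); the best-Q partition
  is kept, and label alignment across partitions uses an exact assignment
  on the module-overlap contingency table (subset dynamic programming up
  to 16 modules, greedy beyond).
* Module IDs are 1-based contiguous integers, the R convention.

Consensus modules take, per node, the label most frequently assigned
across aligned partitions, ties resolving to the lowest label.

## The synthetic benchmark generator

Real mesoscale connectomes (tracer-derived or tractography-derived mouse
brain graphs) are not redistributable at this scale, so the package ships
a generator whose defaults emulate their statistical structure and whose
ground truth makes every pipeline stage testable:

* **Layout.** 286 regions: 143 sampled uniformly in the right half of a
  5.7 × 4.1 × 3.3 mm semi-axis ellipsoid and mirrored across the
  midsagittal plane, with lognormal region volumes (meanlog `log 1.5`,
  sdlog 0.6 mm³). Twelve anterior-to-posterior division labels of equal
  node count stand in for major brain divisions.
* **Fiber distances.** `f = τ·Euclidean·exp(jitter·η)` with tortuosity
  τ = 1.3 and lognormal jitter SD 0.1, floored at the Euclidean distance
  (a fiber path cannot be shorter than a straight line).
* **Weights.** `log w = g(f) + sd(f)·ε` with a decreasing cubic `g`
  declining ≈ 7 natural-log units across the 0–15 mm distance range and
  noise SD 1 with a mild linear distance gradient
  (`sd(f) = 0.75 + 0.5·f/f_ref`). Together the trend and noise span
  roughly five decades of weight — the dynamic range these connectivity
  matrices display — and the heteroscedastic spread gives the parabola
  `h` genuine structure to fit.
* **Planted modules.** By default the planted partition is the Louvain
  partition of the *unplanted* graph, boosted by `β_m` in log-space.
  Brain modules are spatially coherent; a spatially random partition at
  the benchmark boost is invisible against the geometric community
  background, which would make module-recovery benchmarks meaningless.
  Spatially random bilateral modules and user-supplied assignments remain
  available.
* **Planted hubs.** The top 15% of nodes by distance from the
  volume-weighted center of mass receive a log-weight boost on their
  incident edges of `β_h·(0.5 + f/f̄)` (doubled for hub–hub edges). The
  distance-proportional term matters: a flat boost cancels exactly in the
  weight-weighted mean neighbor distance, whereas peripheral hubs in
  tracer data are distinguished precisely by holding long-range
  connectivity. A flat-profile option implements the plain boost.

What the generator does *not* emulate: modality-specific weight units,
asymmetric or directed connectivity, distance-dependent reconstruction
*bias* (tractography's long-range underestimation), inter-animal
variability, or anatomically realistic division geometry. Passing
benchmarks therefore demonstrates that the pipeline recovers the kinds of
geometric and non-geometric structure these networks exhibit, not that
any particular empirical dataset behaves identically.

## The workflow and its defaults

`run_analysis()` composes the stages: per graph it fits the trend, builds
100 geometric and 100 random surrogates, computes raw and
surrogate-normalized modularity, consensus modules, centralities,
hub tables (strength- and eigenvector-defined, top 15%), center-of-mass
peripherality with Tukey range tests, weight-weighted mean neighbor fiber
distances with the hub/feeder split, 1 mm-binned z-scored weight-distance
profiles, and binary global efficiency across a 21-point density grid
from 0.05 to 1 normalized against both ensembles, with permutation tests
(999 permutations) between the ensembles per density. Local efficiency
and clustering/path-length tables are computed for empirical graphs
across the same grid (per-surrogate neighborhood subgraphs at every
density would dominate runtime without informing the normalisation the
workflow reports). With a designated reference graph it adds overall and
per-division-pair Spearman weight agreement, module-assignment agreement,
and — given at least two non-reference graphs as replicates — per-bin
one-sample t-tests of their profiles against the reference.

Every stochastic step derives its seed deterministically from the master
seed, so a report is a pure function of (graphs, config, seed) and
serializes to byte-identical JSON across reruns. The test suite exercises
the full pipeline on two 286-node benchmarks with 100+100 surrogates each
and asserts the rerun identity on a reduced configuration of the same
fixtures; the problem sizes quoted throughout (286 nodes, 100 surrogates,
20 refits for ensemble trend variability, 50 surrogates for the
eigenvector hub split) are the package's chosen benchmark conditions.

## Interpreting the headline quantities

* `Q_emp / mean(Q_geo)` ≈ 1 on a purely geometric benchmark (the
  calibration regime) and significantly above 1 when non-geometric
  modular structure is present; the empirical rank of `Q_emp` within the
  ensemble gives the p-value.
* Empirical hubs farther from the center of mass than surrogate hubs —
  with Tukey's range test on the pooled hub distance distributions —
  indicates hub placement beyond geometric expectation (the tracer-like
  pattern); surrogate-like placement indicates geometric determination
  (the tractography-like pattern).
* A hub/feeder ordering of mean neighbor fiber distance that *flips*
  between the empirical graph and its surrogates is the same contrast seen
  through connection lengths: peripheral hubs hold long-range edges that
  the geometric null cannot reproduce.

## Known limitations

* Surrogates are undirected and nonnegative; no degree-preserving binary
  rewiring (Maslov–Sneppen) null is provided.
* Strength restoration at tolerance `1e-3` perturbs the rank-mapped
  weight multiset slightly; exact multiset preservation holds only
  pre-restoration.
* The random-surrogate trend is flat in expectation but individual
  refits scatter (SD ≈ 0.3 log-units at benchmark scale); single
  surrogates should not be over-interpreted.
* The permutation and rank p-values are bounded below by `1/(n+1)`; with
  100 surrogates the smallest attainable p is ≈ 0.0099.
* Label alignment beyond 16 modules falls back to a greedy matching that
  is not guaranteed optimal.

## A minimal session

```{r example, eval = FALSE}
bench <- make_benchmark(synthetic_spec(
  n_nodes = 286, modules = "intrinsic",
  hub_fraction = 0.15, seed = 1
))
pure <- make_benchmark(synthetic_spec(n_nodes = 286, seed = 2))
report <- run_analysis(
  list(planted = bench$graph, pure = pure$graph),
  reference = "planted", seed = 99
)
report
write_report(report, "results/")
```
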