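# geonull

Geometric surrogate null models for spatially embedded brain networks.

## The problem

Structural connectomes live in physical space: connection weights decay
steeply with the fiber distance between regions, and reconstruction methods
— diffusion tractography especially — underestimate long-range
connectivity. Modules, hubs and efficient layouts can therefore arise from
geometry alone. Before interpreting such features as organisational
principles of the brain (or as a reconstruction method's achievement), one
should ask how much of them a purely geometric network would already show.

`geonull` answers that question for any weighted symmetric connectome with
node coordinates, region volumes and a fiber-distance matrix. It is aimed
at researchers validating tractography pipelines against tracer-derived
connectivity and, more generally, at anyone benchmarking weighted
spatially embedded networks against distance-aware nulls.

## The method

For an empirical graph `W_emp` with fiber distances `f`:

1. fit `log w_ij ≈ g(f_ij)` (cubic) and a parabola `h(f)` to the absolute
   residuals;
2. detrend: `r_ij = (log w_ij − g(f_ij)) / h(f_ij)`;
3. shuffle the residuals over the positive edge positions;
4. retrend, then replace the values with the original weight multiset
   mapped through rank order;
5. restore the empirical node-strength distribution by multiplicative
   symmetric scaling sweeps, `w_ij ← w_ij √((t_i/s_i)(t_j/s_j))`.

The result is a **geometric surrogate** `W_geo`: same strength
distribution, same low-order weight–distance relationship, all other
topology destroyed. A **random surrogate** `W_rand` (steps 3 and 5 only)
preserves the strength distribution alone. Empirical metrics are then
normalized by ensemble means — `Q_emp / mean(Q_geo)` equal to 1 means the
metric is fully explained by spatial embedding; ratios above 1 quantify
structure beyond geometry. The same logic is applied to hub placement
(distance of top-15% strength nodes from the brain's center of mass), the
hub/feeder split of mean neighbor fiber distance under eigenvector
centrality, and binary global efficiency across edge-density thresholds,
with Tukey range tests and permutation tests for the comparisons.

Because suitable empirical datasets are large and not redistributable, the
package includes a synthetic benchmark generator (`make_benchmark()`)
producing bilaterally mirrored, near-fully-connected, log-normally
weighted networks with a known distance trend and optional planted modules
and peripheral hubs — every claim in the test suite is checked against
this ground truth.

## Worked example

```r
library(geonull)

# two 60-region benchmarks: one with planted (non-geometric) structure,
# one purely geometric
planted <- make_benchmark(synthetic_spec(
  n_nodes = 60, modules = "intrinsic", hub_fraction = 0.15, seed = 1
))
pure <- make_benchmark(synthetic_spec(n_nodes = 60, seed = 2))
planted$graph
#> <spatial_graph> 60 regions (30 L / 30 R), 12 divisions
#>   1770 / 1770 node pairs connected (density 100.0%), fiber distances 0.36-16.07 mm

report <- run_analysis(
  list(planted = planted$graph, pure = pure$graph),
  reference = "planted",
  config = analysis_config(n_surrogates = 50, densities = c(0.2, 0.5, 1)),
  seed = 7
)
report
#> <analysis_report> 2 graph(s), reference 'planted', seed 7
#>   planted: Q = 0.447 (Q/Q_geo = 1.439, Q/Q_rand = 1.606)
#>   pure: Q = 0.363 (Q/Q_geo = 1.051, Q/Q_rand = 1.694)
```

The planted graph's modularity exceeds its geometric null by ~44% — the
planted intra-module boost is structure geometry cannot explain — while
the purely geometric graph sits at a ratio of ~1.05, i.e. essentially
fully geometrically determined. The planted peripheral hubs show the same
contrast in space:

```r
report$graphs$planted$hubs$summary[, c(
  "hub_com_distance", "hub_com_distance_geometric"
)]
#> # A tibble: 1 × 2
#>   hub_com_distance hub_com_distance_geometric
#>              <dbl>                      <dbl>
#> 1             4.86                       2.36
```

Empirical hubs sit 4.9 mm from the center of mass; the geometric
surrogates place theirs at 2.4 mm — hub peripherality beyond geometric
expectation, the pattern tracer-derived connectomes show and
tractography-derived ones lose. `write_report(report, dir)` serializes
everything (deterministically, byte-identical per seed) to JSON and TSV;
`autoplot()` methods and `plot_*()` helpers cover the profile, ensemble
convergence, efficiency curves and node maps. A thin command-line wrapper
with `simulate` / `surrogate` / `metrics` / `report` subcommands lives at
`inst/cli/geonull`.

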