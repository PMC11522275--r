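# asebio

Multi-temporal ecosystem-service (ES) assessment on categorical land-cover
grids, and the comparison of model-based ES potential with stakeholder
perceptions.

## The problem

Landscape planners need to know how the capacity of a territory to supply
ecosystem services — climate regulation, water purification, habitat quality,
drought regulation, recreation, food provisioning, erosion prevention,
pollination — changes through time, and whether the numbers produced by
biophysical models agree with how experts and stakeholders perceive the same
landscape. `asebio` implements that assessment chain for CORINE-style
land-cover data:

1. **Normalization.** Raw per-ES potential layers (arbitrary biophysical
   units) are min-max scaled to a common [0, 1] potential scale, pooled
   across epochs so temporal trajectories stay comparable.
2. **Temporal change.** Per-pixel percent change between a baseline and a
   final epoch,

   `CES_x = (ES_final,x − ES_baseline,x) / ES_baseline,x × 100`,

   classified into five classes by standard deviations of the change
   distribution (strong decline ≤ −1.5 SD, decline, stable (−0.5, 0.5),
   improvement, strong improvement ≥ 1.5 SD) and aggregated to zones
   (NUTS-3 analogues).
3. **Stakeholder weights (AHP).** 0–9 importance scores per ES are
   aggregated (geometric mean), turned into a reciprocal pairwise
   comparison matrix `a_ij = s_i / s_j` on Saaty's [1/9, 9] scale, and
   prioritised by the principal eigenvector; the consistency ratio
   `CR = (λ_max − n) / ((n − 1)·RI)` reports judgment coherence.
4. **Composite index.** The weighted overlay

   `Index = Σ_i w_i · ES_i`

   combines the eight normalized layers into a single [0, 1] composite
   per epoch, with per-ES and per-land-cover contribution summaries and
   boxplot statistics across epochs.
5. **Perception mapping.** A land-cover capacity matrix (0–5 expert scores
   of each class's capacity to supply each ES) is aggregated by geometric
   mean, normalized by the scale maximum, and applied to the land-cover map
   by lookup; the perceived layers are combined with the same weights into
   a stakeholder perception index.
6. **Agreement statistics.** Pearson correlation matrices within and between
   the two approaches (class-mean or pixel support), per-ES mean differences,
   the overall percent difference of the two composites, a paired t-test
   over per-ES means, and one-way ANOVA across epochs with Shapiro–Wilk
   normality checks.

A seeded synthetic-landscape generator (spatially autocorrelated land cover
with controlled class transitions, class-conditional ES layers with Gaussian
noise, multi-stakeholder score tables with controlled dispersion, contiguous
zones) provides known ground truth, so the whole chain runs and is testable
without any external download.

## Worked example

```r
library(asebio)

cfg <- pipeline_config(
  synthetic_config(grid_rows = 120, grid_cols = 120, seed = 42),
  n_zones = 23
)
res <- run_pipeline(cfg)

res$weights
#> <ahp_weights> n = 8, lambda_max = 8.000000, CR = 0.0000
#> # A tibble: 8 × 2
#>   es_id weight
#>   <chr>  <dbl>
#> 1 CR    0.140
#> 2 WP    0.167
#> 3 HQ    0.135
#> 4 DR    0.193
#> 5 R     0.0223
#> 6 FP    0.123
#> 7 EP    0.117
#> 8 P     0.101

res$report
#> <comparison_report>
#>   overall percent difference: +14.7%
#>   paired t: t = 3.338, df = 7, p = 0.01245
```

The weights recover the configured stakeholder priorities (drought
regulation most important, recreation least; `CR = 0` because the simulated
panel is internally consistent). The comparison report shows the effect of
the configured stakeholder inflation (`perception_inflation = 0.2`): the
perception index sits about 15% above the model index and the paired t-test
flags the systematic gap, while the per-ES differences (`res$report$per_es`)
are positive for seven of the eight services on this landscape.

Each result is a tibble (or has `tidy()`/`glance()` methods), so it drops
straight into a dplyr/ggplot2 workflow; `autoplot()` is provided for index
distributions and change-class maps, plus `plot_class_potential()` and
`plot_correlation_matrix()`.

A thin command-line wrapper with `simulate`, `weights` and `run` subcommands
is installed at `inst/cli/asebio.R`.

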