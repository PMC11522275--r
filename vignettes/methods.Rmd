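---
title: "Methods: ES potential, stakeholder weighting and the composite index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ES potential, stakeholder weighting and the composite index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asebio)
```

This vignette documents the models and procedures the package implements,
the choices made where the methodology was genuinely open, and what the
synthetic-landscape tests do and do not demonstrate about real data.

## The assessment chain

The package assesses the potential of a landscape to supply eight ecosystem
services (ES) — climate regulation (CR), water purification (WP), habitat
quality (HQ), drought regulation (DR), recreation (R), food provisioning
(FP), erosion prevention (EP) and pollination (P) — on a common categorical
land-cover grid across several epochs, then confronts the model-based
picture with a stakeholder-based one.

### Normalization

Raw ES layers arrive in heterogeneous biophysical units (tonnes of carbon,
retention fractions, visitation proxies). `normalize_stack()` min-max scales
each ES to [0, 1] using the *pooled* minimum and maximum across all epochs
of that ES. Pooling is a deliberate choice: scaling each epoch by its own
extremes would re-base the scale every year and distort both the temporal
change index and class trajectories; a `mode = "per_epoch"` flag exists for
sensitivity analysis. Observed extremes (not theoretical bounds) define the
scaling because generic biophysical outputs have no universal bounds.
Nodata pixels are excluded from the extremes and from every mean. A constant
stack has no meaningful scale and is an error naming the ES.

### Temporal change

`change_index()` computes, per pixel,
$\mathrm{CES} = \frac{ES_{final} - ES_{baseline}}{ES_{baseline}} \times 100.$
The ratio is undefined at zero baseline. We mask such pixels (tolerance
$10^{-12}$) and count them, rather than substituting an epsilon: any epsilon
would dominate the statistic exactly where the data are least informative.

`classify_change()` standardizes the change values per ES over valid pixels
($z = (\mathrm{CES}-\bar{\mathrm{CES}})/s$) and assigns five classes:
strong decline $z \le -1.5$, decline $-1.5 < z \le -0.5$, stable
$-0.5 < z < 0.5$, improvement $0.5 \le z < 1.5$, strong improvement
$z \ge 1.5$ — closed on the outer side of each non-stable class, mirrored
about zero. Standardization is per ES (not across all ES jointly), so each
service's change map is read against its own variability; because z-scores
are affine-invariant, the classification does not depend on the units of
the change values. Note the reference distribution is the empirical change
field itself: with heavy-tailed percent changes (small baselines inflate the
SD) the stable class can far exceed the Gaussian 38.3% share, which is
expected behaviour, not a bug.

`zonal_mean()` aggregates any layer to zones by unweighted pixel means —
pixels are equal-area on the common grid — and flags, rather than zeroes,
zones with no valid pixel.

### Stakeholder weights (AHP)

Stakeholders score each ES's importance on a 0–9 scale. The path from
scores to weights is not fully dictated by standard practice, so the
package makes three documented choices:

* **Aggregation.** Geometric mean across stakeholders (the standard
  group-AHP aggregation, order-preserving and scale-coherent). An
  alternative (`method = "per_stakeholder"`) builds one pairwise matrix per
  stakeholder and combines matrices by element-wise geometric mean; with
  identical panels the two coincide.
* **Ratios.** The pairwise comparison matrix is $a_{ij} = s_i / s_j$,
  clipped symmetrically to Saaty's $[1/9, 9]$ scale (reciprocity is enforced
  after clipping).
* **Zero scores.** A zero importance would make ratios degenerate; the
  default floors 0 at 0.5 (half the minimal positive step), preserving
  "near-zero importance" while keeping the matrix positive. Zero
  propagation is available behind a flag.

`compute_weights()` uses the canonical principal-eigenvector
prioritisation, by power iteration at relative tolerance $10^{-10}$ (at
most 10,000 iterations; reciprocal positive matrices make this a
well-behaved primary-eigenvalue problem). The consistency ratio is
$CR = \frac{\lambda_{max} - n}{(n-1)\,RI_n}$ with Saaty's random indices
$RI_{1..10} = 0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49$; for
$n \le 2$ a reciprocal matrix is consistent by construction and $CR = 0$.
For perfectly consistent matrices the eigenvector equals any normalized
column, which the tests assert to $10^{-10}$.

`default_weights()` ships a reference weight configuration in which drought
regulation carries the highest weight (0.17) and recreation the lowest
(0.04), the two published values of the stakeholder exercise this package
generalises; the remaining mass is split equally across the other six ES as
an explicit placeholder, because only those two weights are published. Any
complete weight tibble can be supplied instead.

### The composite index

`compute_index()` forms the per-pixel weighted overlay
$\mathrm{Index} = \sum_i w_i \, ES_i$ with $\sum_i w_i = 1$, a convex
combination: the index is bounded by the inputs and linear in them (both
are tested against brute-force oracles at $10^{-12}$). A pixel missing any
contributing ES is invalid by default; re-normalizing the weights over the
ES present at each pixel (`renormalize_missing = TRUE`) is offered but not
default, because it silently varies the effective weighting across space.
Distribution summaries use type-7 (linear interpolation) quantiles — the
convention matters for boxplot-style statistics and is therefore pinned and
documented. Contribution shares are
$w_i \overline{ES_i} / \sum_j w_j \overline{ES_j}$ over jointly valid
pixels.

### Perception mapping

The stakeholder counterpart scores each land-cover class's capacity to
supply each ES on a 0–5 scale. `aggregate_capacity()` takes the geometric
mean across stakeholders and normalizes by the fixed scale maximum 5. Two
policies deserve note:

* **Zero propagation** is the default: the geometric mean of any cell
  containing a 0 ("no potential at all") is 0. This respects the absolute
  anchor of the scale; a 0.5-floor alternative mirrors the AHP policy.
* **Scale-maximum normalization** (divide by 5) preserves the absolute
  meaning of the anchors; per-ES min-max over observed cells is available
  behind a flag but makes the best-scored class always 1 regardless of how
  highly it was actually rated.

`apply_matrix()` is an exact per-pixel lookup, so perceived layers are
piecewise constant on land-cover patches, and applying
`class_potential_summary()` to a perceived layer returns the capacity
column exactly (a round-trip identity the tests assert). The combined
perception index reuses `compute_index()` unchanged. Because the published
exercise reports a "consistency ratio" without describing a pairwise
structure for the capacity scores, `judgment_consistency()` reports
dispersion diagnostics (coefficient of variation per cell and per ES) and
offers an optional AHP-style ratio built from per-class mean scores.

### Agreement statistics

`raster_correlation()` is Pearson's r over jointly valid pixels.
`correlation_matrices()` defaults to *class-mean support* — one point per
land-cover class — for the within- and cross-approach matrices, because the
perceived layers are functions of class alone and pixel-support correlations
against them mostly re-measure patch geometry; pixel support is available
behind a flag and both are labelled in the output. Per-ES differences are
plain differences of means (stakeholder − model, positive when stakeholders
rate higher), reported at full precision and at 2 decimals. The overall
percent difference divides by the model mean (the natural reading of
"X% higher than the model estimate"); the other denominator is a flag. The
paired t-test and one-way ANOVA are the classical procedures
(`stats::t.test`, equal-variance `stats::oneway.test`), with Shapiro–Wilk
per group; Shapiro–Wilk caps at 5,000 observations, so larger groups are
deterministically subsampled and flagged in the output. p-values are
reported at machine precision and no multiple-testing correction is applied
(none is part of the assessed methodology).

## The synthetic-landscape generator

The generator exists so that every downstream stage has known ground truth.

* **Land cover.** One independent Gaussian random field per class is
  smoothed to the configured autocorrelation length (`smoothing_scale`,
  cells; default 5), mapped through its marginal CDF to a Gumbel variate,
  and the pixel's class is $\arg\max_k(\log a_k + g_k)$ where $a_k$ is the
  class affinity. The Gumbel-max construction makes expected areal shares
  exactly proportional to affinity while the smoothed fields produce
  contiguous, CORINE-like patches; a plain argmax over scaled Gaussian
  fields would not give proportional shares. Later epochs flip a
  `transition_rate` fraction (default 0.05 per step) of patch-boundary
  pixels to a neighbouring patch's class — gradual boundary change, not
  salt-and-pepper noise.
* **Classes.** The default set is a 12-code subset of the CORINE level-3
  nomenclature spanning all five level-1 categories, large enough to
  exercise class summaries without 44-class bloat.
* **ES layers.** Pixel value = true class capacity + Gaussian noise
  (`noise_sd`, default 0.1 on the [0, 1] scale), clipped to [0, 1]. With
  zero noise the class summaries recover the truth table exactly — the
  parameter-recovery hook the tests rely on. The clipping matters: the CLT
  recovery bound $3\sigma/\sqrt{n}$ only applies when capacities are far
  (≥ 4σ) from the bounds, which the recovery tests enforce by drawing
  truths in [0.4, 0.6]; near-bound capacities acquire a clipping bias of up
  to ~0.03 at σ = 0.1, which is realistic (models saturate) but must not be
  confused with estimator error.
* **Stakeholders.** Integer scores are the truths plus Gaussian noise
  (`score_dispersion`, default 1 step), rounded and clamped to the scale
  (0–9 importance, 0–5 capacity). 30 stakeholders by default, the size of a
  typical expert workshop. Clamping slightly biases means near the scale
  ends, which the recovery tests absorb inside their ±0.75 band.
* **Zones.** `n_zones` seed pixels (default 23, a mainland-Portugal-like
  NUTS-3 count) grown by breadth-first expansion, guaranteeing a contiguous
  partition of the valid mask.
* **Determinism.** Every generator draws through an internal seeded RNG
  scope, so identical configurations give bit-identical outputs and the
  caller's RNG stream is never disturbed.

What passing tests on these landscapes show: the arithmetic, invariances
and statistical contracts of every stage, end-to-end, under known truth.
What they do not show: fidelity to real CORINE change statistics, real
biophysical model behaviour (spatial covariance beyond class membership,
anisotropy, autocorrelated errors), or real stakeholder behaviour
(systematic biases other than the configurable uniform inflation,
correlations between panellists). National-scale published values
(index medians, specific correlations and test statistics) depend on those
real inputs and are deliberately not targets of the synthetic suite; the
suite instead checks the qualitative signature — a uniform +0.2 capacity
inflation must surface as a positive overall gap, positive per-ES
differences and positive cross-approach correlations.

## Numerical choices and degenerate inputs

* Power iteration: relative tolerance $10^{-10}$, max 10,000 iterations;
  $\lambda_{max}$ clamped at $n$ before the consistency index so floating
  point cannot produce a negative ratio.
* Baseline-zero masking tolerance $10^{-12}$; masked counts reported.
* Quantiles: type 7. Correlations need ≥ 3 joint pixels and nonzero
  variance. ANOVA on fully constant data returns F = 0 rather than NaN.
* Weighted sums accumulate in double precision; oracle agreement is
  asserted at $10^{-12}$ on random stacks.
* Grids are matrices with `NA` nodata plus explicit alignment checks
  (dimensions and cell size) before any cross-layer operation; class codes
  are stored as strings in memory and as integer ids with a code↔label
  sidecar CSV on disk (raster bands are numeric).

## Problem sizes

The test suite and the reproduction script use 200 × 200-cell landscapes
(40,000 pixels at 100 m — a 20 × 20 km tile), five epochs, eight ES,
12 classes, 30 stakeholders and 23 zones; unit tests use 40 × 40 to 100 ×
100 grids. These sizes give Monte-Carlo bounds (CLT class-mean recovery,
null correlation bounds, ANOVA type-I error at 1,000 replicates) enough
resolution to be sharp while the full suite stays fast; the pipeline scales
linearly in pixels × ES × epochs.

## Known limitations

* The change classification inherits the ambiguity of SD-threshold schemes:
  with skewed change distributions the five classes are not equally
  meaningful; the per-ES empirical standardization is documented, not
  canonical.
* AHP weights from aggregated scores are one of several defensible group
  procedures; the per-stakeholder alternative is provided but both share
  the ratio-matrix construction from a single score vector, which caps
  attainable inconsistency relative to a fully elicited pairwise exercise.
* The perception map is class-resolved by construction: within-class
  spatial variation of perceived potential is not representable.
* ASCII-grid I/O carries no coordinate reference system; all layers are
  assumed to share one grid, which the package checks only by shape and
  cell size.
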