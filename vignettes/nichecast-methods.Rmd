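---
title: "Ensemble niche modelling and climate-scenario projection with nichecast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble niche modelling and climate-scenario projection with nichecast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecast)
```

## The problem

Presence-only occurrence records — compilations from public biodiversity
databases — are the main evidence available for mapping where a marine
species can live. `nichecast` implements an ensemble species distribution
modelling (SDM) pipeline that turns such records, together with gridded
environmental climatologies, into a per-cell **Environmental Suitability
Index (ESI)** in $[0,1]$, and projects that index under future climate
scenarios from multiple general circulation models (GCMs) and emission
pathways (RCP2.6 / 4.5 / 8.5). The pipeline rests on two standard working
assumptions of correlative SDMs: niche conservatism (the realized niche is
stable over the projection horizon) and the equilibrium hypothesis (the
species occupies the suitable space accessible to it).

Every stage is exercised end-to-end on a synthetic world with a known niche
truth, so the statistical behaviour of the whole chain — not just its parts —
is testable without downloading any real data.

## Pipeline stages

### Occurrence preparation

Raw records (`species, lon, lat, year, flag`) pass a quality-control chain:
unreliable-source flags are dropped; exact duplicates (coordinates rounded
to 4 decimals, plus year) are removed; on-land and out-of-domain points are
removed; records from 1990 onwards are kept unconditionally while older or
undated records are kept only within `edge_distance` (default 100 km) of a
recent record, so a distribution edge must be confirmed by recent data;
finally, isolated records with no neighbour within `outlier_distance`
(default 1000 km) are treated as locational errors. The isolation rule uses
a mutual-witness criterion (a record survives iff another record lies within
the radius) rather than a density envelope, because the mutual-witness form
is provably idempotent — cleaning a cleaned set changes nothing — which we
treat as a hard contract of the stage. Survivors are aggregated to one
presence per occupied 0.1° cell, cells being half-open intervals
$[\text{edge}, \text{edge} + 0.1)$.

A hierarchical habitat filter then restricts both presences and candidate
prediction cells: a marine cell is admissible iff its depth lies within the
species' observed depth range **or** it lies within 50 km of the coast (the
coastal buffer keeps shelf-poor near-coastal seas available).

### Environmental space, thinning and pseudo-absences

Candidate covariates are pruned greedily in a fixed priority order, keeping
a variable only if its absolute Pearson correlation with every
already-kept variable is $\le 0.7$. Presences are then thinned in
environmental space: axis-aligned bins of width 0.5 (°C for
temperature-type variables, psu for salinity, 0.5 log units for primary
production — the width is applied on the log scale, which keeps the bins
scale-free) retain a single presence each. The within-bin representative is
the record with the most recent year, ties broken by lowest cell id, making
thinning deterministic and order-invariant.

Pseudo-absences are drawn outside the **trimmed convex hull** of the thinned
presence environments: each variable is first clipped to its
$[2.5, 97.5]$ percentile interval (damping the influence of extreme first
records), the hull of the survivors is taken, and exactly as many
pseudo-absences as thinned presences are sampled uniformly without
replacement from the admissible marine cells whose environments fall
strictly outside the hull. Sampling from realized cell environments (rather
than abstract space) means every pseudo-absence maps to a geographic cell.
Hull membership is decided by a phase-1 simplex feasibility test
($x \in \mathrm{conv}(P)$ iff $\exists \lambda \ge 0$, $\sum\lambda = 1$,
$P^\top\lambda = x$) on coordinates standardised to half-range units, with
tolerance $10^{-9}$; boundary points count as inside. Rank-deficient point
sets fall back to a bounding-box test with a warning.

### Candidate algorithms

Eight algorithms share one fitting interface and one contract — predictions
in $[0,1]$ for any finite environmental point:

| id | backing | frozen defaults |
|------|-----------------------------------|--------------------------------|
| NPPEN | own implementation (below) | — |
| GLM | `stats::glm` | binomial logit, linear + quadratic terms |
| GAM | `mgcv::gam` | binomial, spline basis `k = 4` per variable |
| GBM | `xgboost` | 2500 trees, depth 3, shrinkage $10^{-3}$ |
| ANN | `nnet` | 1 hidden layer of 5 units, 3 restarts |
| FDA | `MASS::lda` on a quadratic polynomial basis | — |
| MARS | own implementation | degree 2, $\le$ 15 hinge terms, GCV pruning |
| RF | `randomForest` | 500 trees, class-vote fractions |

The defaults are versioned in `algorithm_defaults()` rather than inherited
silently from the backing packages. FDA and MARS produce scores mapped to
$[0,1]$ through a logistic link and clamped, honouring the ESI contract.
The MARS implementation is a compact forward/backward hinge-basis learner:
reflected pairs $\max(0, x-t)/\max(0, t-x)$ grown by residual sum of
squares, pruned by generalised cross-validation (penalty 3), and refitted as
a binomial GLM on the surviving basis so its output is a calibrated
probability. FDA uses optimal-scoring discriminant analysis on linear,
square and pairwise-product terms, which for two classes is equivalent to
flexible discriminant analysis with a quadratic regressor.

**NPPEN** (Non-Parametric Probabilistic Ecological Niche model) is the one
presence-only member and is implemented from first principles. Given the
reference matrix $X$ of thinned presence environments with mean $\mu$ and
covariance $\Sigma$, a query point scores
$D^2(x) = (x-\mu)^\top \Sigma^{-1} (x-\mu)$ and
$$\mathrm{ESI}(x) = \frac{1}{n}\,\#\{\,y \in X : D^2(y) > D^2(x)\,\},$$
the rank-based probability of membership. The index is 1 at the niche
centroid, 0 beyond the most extreme reference point, and invariant under
invertible affine transforms of the environmental axes (a property of the
Mahalanobis form that the test suite asserts numerically). A singular
covariance is ridge-regularised ($\varepsilon I$, $\varepsilon = 10^{-8}$)
with a warning. The test suite pins this implementation against a
brute-force Monte-Carlo permutation oracle that recomputes the quadratic
form independently; we deliberately do not use a swap-the-query-in
substitution oracle, because at a 50-point reference the insider/outsider
covariance asymmetry biases that estimator by up to $\sim$0.1 at moderate
distances — it estimates a different quantity.

### Evaluation and ensemble selection

`esm()` runs 10 independent random 70/30 splits; each algorithm is fitted
on every training split and scored on the held-out 30% with the
**Continuous Boyce Index (CBI)**: windows of width 0.1 slide across the
suitability axis at 101 positions; per window the predicted-to-expected
ratio is the fraction of presence predictions inside divided by the
fraction of background predictions inside; the index is the Spearman
correlation between window midpoints and P/E over windows with positive
expected mass (empty windows are dropped, not imputed). The background is
the held-out presence/pseudo-absence set itself — the presence/pseudo-absence
formulation of the metric. An availability background (all admissible
cells) is available via the `background` argument but is not the default:
rank-calibrated models such as NPPEN have presence predictions that are
uniform on $[0,1]$ rather than concentrated near 1, and an availability
background provably flattens their P/E curve even when the ranking is
perfect.

Response curves (the model profiled along one covariate, the others at
training medians) are screened for ecological plausibility: after a
3-point running mean, the curve is decomposed into significant alternating
extrema — direction reverses only on a move exceeding a 0.02 ESI
tolerance — and passes iff it has at most one interior maximum. Bimodal
temperature responses, the canonical spurious shape, fail; monotone and
flat curves pass. In practice the step-noise of the tree ensembles (GBM,
RF) often fails this screen while the smooth learners pass, mirroring the
common experience that tree ensembles need additional smoothing before
their response shapes are interpretable.

An algorithm is retained iff its mean CBI across the 10 runs exceeds 0.5
**and** all its response curves pass. The retained set defines the
ensemble; an empty set is a hard error.

### Climate preparation and projection

Future fields come per (GCM, RCP, decade), with decades 2030–2039,
2050–2059 and 2090–2099 averaged year by year (`decade_average`), bilinear
regridding onto the 0.1° grid (`regrid_bilinear`, nearest-neighbour at the
edge, never extrapolating beyond one coarse cell), and per-cell **delta bias
correction** against the observed climatology:
$$\text{corrected}(c) = \text{future}(c) + \bigl[\text{obs}(c) - \text{model}_{\text{common}}(c)\bigr].$$
The corrected common-period field is then identically the observations
(Pearson $r = 1$, zero centered RMSD, equal SD — verified to machine
precision) and the simulated change signal is preserved exactly. Taylor
statistics (`taylor_stats`) quantify model/observation agreement before and
after correction. Because the additive correction commutes with decade
averaging, averaging-then-correcting equals correcting-then-averaging; the
package averages first. Salinity is held constant in time (its temporal
variability is negligible compared to its spatial role of separating
brackish from marine waters); log primary production is corrected on the
log scale, which is a clamped multiplicative ratio on the raw scale. The
warming delta is applied to mean temperatures (SBT, SST) only — warming a
seasonal range or a monthly variance by the same increment would be
physically wrong.

Ensemble maps are unweighted member means with the member (population)
standard deviation alongside: members are (algorithm × CV run) for the
contemporary map and (algorithm × CV run × GCM) for future maps — 50
simulations per retained algorithm with 10 runs and 5 GCMs. Suitable area
sums latitude-weighted cell areas
$(111.195 \cdot 0.1) \times (111.195 \cdot 0.1 \cos\varphi)$ km² over cells
with ESI at or above a threshold; since no single threshold defines
"suitable habitat" canonically, the range-change table reports a
sensitivity sweep over 0.3 / 0.5 / 0.7 with 0.5 as the headline default.
EEZ summaries are unweighted means over valid cells whose centres fall in
each polygon (cell-centre assignment, each cell counted at most once), with
log₁₀ mean annual catch attached and entries under 1000 t flagged as
below the display threshold but retained in the data.

## The synthetic world

`make_env_grid()` builds a 5° × 5° domain at 0.1° resolution (50 × 50
cells, ~2100 marine) with a sinuous eastern coastline: sea-bottom
temperature falls poleward at 1.8 °C per degree latitude (15–24 °C across
the domain), its annual range peaks at mid-latitudes, surface temperature,
salinity and the variance variables track their parents with enough shared
structure that the \(r > 0.7\) pruning has real work to do (SBTr–SBTvar
correlate at roughly 0.8), and log primary production varies mostly
zonally. Smooth seeded plane-wave textures add spatial heterogeneity so
environmental bins are well populated.

The species truth is a product of independent Gaussians over (SBT, SBTr,
Log_PP) — optima 17 °C, 5 °C, 0.8; tolerances 1.5, 1.5, 1.0 — chosen so
the suitable band sits in the poleward half of the domain with a genuine
cold-side refuge: a 3.2 °C warming (the end-of-century RCP8.5 delta)
pushes the thermal optimum mostly off-domain, while the 0.9 °C RCP2.6
delta shifts it by about half a degree of latitude. Occurrences are
sampled proportionally to truth × effort, with coastal-heavy effort
$1 + 1.5\,e^{-d_{\text{coast}}/75}$, jittered within cells. Year classes
(73% from 1990 on, 11% older, 16% undated) mirror the proportions reported
for compiled occurrence databases, and the noise specification appends 5%
exact duplicates, 2% on-land errors and 2% unreliable-flagged records so
every cleaning rule is exercised at realistic rates. The default sample is
1000 records.

Emulated GCMs are the observed climatology plus a persistent per-cell bias
(smooth field + i.i.d. noise, σ = 0.5 °C, frozen per GCM) plus small
transient noise (σ = 0.1 °C), with prescribed warming deltas monotone
across RCPs within each decade (0.6–0.9 °C in the 2030s up to
0.9 / 1.8 / 3.2 °C in the 2090s). Because the GCM error is exactly
per-cell-additive, the delta correction is exactly sufficient — the design
isolates the correction's contract. Primary production declines mildly with
warming (−2% per °C). EEZs tile the marine domain as latitudinal bands with
a log-normal catch table whose lower tail falls below the 1000 t display
threshold.

What the generator does **not** emulate: real bathymetry or circulation,
brackish-sea salinity dynamics, biotic interactions, temporally drifting
niches, or GCM errors that are not per-cell-additive (e.g. displaced
fronts). Passing tests therefore demonstrate that the machinery is correct
and directionally sound under the stated assumptions, not that any real
species' projection is right.

## Numerical choices and degenerate inputs

* Hull membership: phase-1 simplex with Bland's rule, tolerance $10^{-9}$
  in standardised units; boundary counts as inside, so pseudo-absences are
  strictly outside. Degenerate reference sets fall back to bounding boxes.
* CBI: windows with zero expected mass are dropped; an all-identical
  background or fewer than three informative windows returns `NA` with a
  warning rather than a number.
* NPPEN: singular covariance ridge-regularised; ESI at the reference mean
  is exactly 1; the most extreme reference point itself scores 0 (a known
  and intended boundary property of rank-based indices).
* Curve screen: sub-tolerance wiggles never reverse direction, so a noisy
  but unimodal curve passes; degenerate flat curves pass.
* Cross-validation requires both classes in both partitions and at least
  10 rows per class per fit; violations are errors, not silent successes.
* A failed algorithm fit (singular design, non-convergence) yields a
  flagged `niche_fit_failed` carrying the reason; it is excluded from the
  ensemble and reported, never imputed.
* All stochastic steps derive their seeds from a master seed plus a stage
  label, so stages are independently reproducible and identical
  configurations give bit-identical manifests.

## Problem sizes

The default study conditions — 50 × 50 cells, 1000 occurrence records,
~200 thinned presences, 8 algorithms × 10 cross-validation runs, 5 GCMs ×
3 RCPs × 3 decades — were chosen so a full pipeline run completes in well
under a minute on one core while every selection decision still rests on
hundreds of evaluation points. They are the sizes at which the package's
own validation suite runs; nothing in the implementation assumes them.

## Known limitations

* The CBI's monotone-transform invariance is exact only in the continuum
  limit; with 0.1-wide windows a harsh monotone transform (e.g. cubing)
  can move the index by ~0.1.
* The convex-hull pseudo-absence rule requires enough admissible cells
  outside the hull; a species whose niche spans the whole domain's
  environmental range will raise the documented shortfall error.
* Range-change percentages depend on the suitability threshold; the
  sensitivity sweep is reported precisely because 0.5 is a convention, not
  a law.
* EEZ catch joins are display metadata: the uniform-catch-distribution
  assumption behind per-EEZ interpretation is reported, not modelled.
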