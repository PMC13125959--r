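---
title: "Ensemble species distribution modelling with ensdm: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble species distribution modelling with ensdm: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensdm)
```

## The modelling problem

`ensdm` implements a presence-only ensemble species distribution model (SDM)
of the kind routinely used to assess how climate and land-use change may
reorganise habitat suitability for taxa with opportunistic occurrence records
(for example, GBIF-sourced records of freshwater invertebrate families). The
response is a binary presence / pseudo-absence indicator on a regular 0.1
degree longitude-latitude grid; the predictors are four bioclimatic
summaries — annual mean temperature (BIO1, degrees C), temperature seasonality
(BIO4), annual precipitation (BIO12, mm), precipitation seasonality (BIO15) —
and three fractional land-use layers (Urban, Crop, Pasture, each the
percentage of the cell occupied by that class). Because true absences are
unavailable for presence-only data, the model contrasts presences against
background ("pseudo-absence") cells sampled from an explicitly declared
accessible area.

Two member models are fitted to the same training table:

* a **MaxEnt-style penalized logistic model**: the label is regressed on an
  expanded feature set (linear, quadratic, pairwise-product, and forward /
  reverse hinge transforms of the predictors) with an L1 penalty, and the
  linear predictor $\eta$ is mapped to suitability on the complementary
  log-log scale, $s = 1 - \exp(-\exp(\eta + c))$. This is the
  presence/background reduction of the MaxEnt formulation: the feature
  classes are MaxEnt's defaults and the cloglog output matches the modern
  MaxEnt suitability scale.
* a **random-forest probability classifier**: 500 classification trees with
  `mtry = floor(sqrt(p))` (2 for the seven standard predictors); suitability
  is the averaged class probability of presence, which gives smoother
  surfaces than majority voting.

Predictive skill is estimated by **stratified 5-fold cross-validation**
(equal class representation per fold): per fold we report AUC — the
Mann-Whitney probability that a random presence outscores a random background
point, ties counted one half — and TSS, sensitivity + specificity − 1
evaluated at the threshold that maximises Youden's J. Fold metrics are
aggregated as mean ± sample standard deviation (denominator $k-1$; reported
"mean ± SD" conventions rarely state the denominator, so we fix one).

Members enter the ensemble only if mean CV AUC ≥ 0.90 **and** mean CV TSS ≥
0.70 (both inclusive). Retained members are combined as a weighted mean with
weights proportional to their mean CV AUC, $w_i = \mathrm{AUC}_i / \sum_j
\mathrm{AUC}_j$. Binary habitat maps use the **P10 threshold**: the 10th
percentile of predicted suitability at the calibration presences, so at
least 90% of presences are classified suitable. Member-specific P10s are
derived from each member's own presence predictions; the ensemble P10 is
recomputed from the ensemble's presence predictions, and typically falls
between the member thresholds.

Suitable area is the sum of geodesic cell areas over suitable cells. Cell
areas use the spherical-zone formula
$A = R^2\,\Delta\lambda\,(\sin\varphi_{top} - \sin\varphi_{bottom})$ with
$R = 6371$ km; no geodetic datum is assumed anywhere else either, and all
great-circle distances (1-km thinning bins, the 200-km coastal buffer) use
the same sphere.

## Occurrence handling and background design

Raw records pass four filters, each counted in a report: duplicate
(species, lon, lat) rows are collapsed; records outside the study extent are
dropped; records on non-land cells are dropped when a land mask is supplied;
and records outside the configured year window (default 2014–2024, so
occurrences reflect contemporary conditions) are dropped. Spatial
autocorrelation is then reduced by keeping **one record per 1 km × 1 km
bin** on a local metric grid (longitude scaled by the cosine of each
record's latitude — adequate at kilometre scale without a projected CRS).
The retained record is the lexicographically smallest (year, lon, lat) in
the bin: a deterministic, seed-free rule, chosen over stochastic thinning so
that thinning is exactly idempotent and testable. Thinned records are
aggregated to the modelling grid (half-open cell intervals; a cell counts
once however many records it holds).

Pseudo-absences are drawn **at cell level**, uniformly without replacement,
at twice the number of presence cells (the 1:2 presence:background design),
from one of two accessible areas: the full valid model domain, or a
**coastal buffer** of all cells whose centers lie within 200 km great-circle
distance of a coast cell — the appropriate accessible area for
coastal-estuarine taxa, which avoids inflating apparent skill with
environmentally distant background. Presence cells are always excluded from
the background so no cell carries both labels. Rows with any missing
predictor are discarded (and counted) when the training table is built.

## Synthetic landscapes and virtual species

The generator gives every downstream stage a ground-truthed input and
defines the package's study conditions:

* **Predictor stack**: Gaussian random fields produced by separable kernel
  smoothing of white noise (simple, dependency-light, stable per seed), with
  a correlation length of 6 cells by default. BIO1 rides a south-warm
  latitudinal gradient (−5 to 22 degrees C); BIO4, BIO12 and BIO15 are
  independent fields around realistic magnitudes; Urban/Crop/Pasture are
  logistic-squashed fields on the 0–100% scale, with Urban concentrated near
  the simulated coast.
* **Coastline**: the landmass ends at a smoothly meandering eastern
  boundary; the easternmost land cell per row is the coast, and cells east
  of it are ocean (masked).
* **Virtual species**: per-predictor response curves (Gaussian, logistic,
  linear or flat) combined by product or geometric mean into a true
  suitability surface in [0, 1]. The default taxon is a narrow-niche species
  with Gaussian responses on BIO1 (optimum 18 degrees C, breadth 1.8) and
  BIO12 (optimum 1500 mm, breadth 300), product-combined on a 100 × 100 grid.
  The breadths were fixed once, while designing the generator, so that the
  taxon is genuinely "strong signal": across seeds both members
  cross-validate at AUC ≈ 0.93–0.95, the discrimination regime these
  workflows are designed for. With 300 presences this run takes well under a
  minute on one CPU.
* **Presence sampling**: cells are drawn without replacement with
  probability proportional to true suitability — presence-only sampling with
  detection proportional to local suitability — then jittered within the
  cell and assigned a year uniform on 2014–2024.
* **Scenarios**: affine perturbations (BIO1 offset, BIO12 scaling, additive
  land-use trends re-clipped to [0, 100]) stand in for future climate-land-use
  stacks. They exercise every projection code path; they do not emulate any
  climate model's spatial structure.

What passing tests on this landscape do **not** show: robustness to
taxonomic error, sampling bias correlated with accessibility, predictor
measurement error, dispersal limitation, or niche non-stationarity — none of
which the generator emulates. Ground-truth recovery here demonstrates that
the machinery is correct, not that any real-data application is.

## Numerical choices

* **Grid conventions.** Row 1 is the northernmost row; cells are
  center-registered; point-to-cell assignment uses half-open intervals
  [edge, edge + resolution), so boundary points are assigned deterministically.
  Extents that are not an integer multiple of the resolution are expanded
  outward (east/north).
* **Resampling.** Bilinear interpolation (exact on affine fields,
  identity on coincident grids) for continuous layers; nearest-neighbour for
  masks and categorical layers, with center ties going to the west/north
  cell. Bilinear output cells outside the source-center hull, or touching a
  nodata source cell, are masked; land-use layers are re-clipped to
  [0, 100] after resampling because bilinear interpolation cannot overshoot
  but ingest from other tools may.
* **Quantiles.** The binding contract for P10 is coverage: at least 90% of
  calibration presences must score at or above it. Among the interpolated
  order-statistic conventions, the default `type = 7` (position
  $h = (n-1)p + 1$) violates that contract for most n (at n = 15 it keeps
  only 13/15 = 86.7% of presences), so `p10_threshold()` interpolates at
  $h = (n+1)p$ (`type = 6`), which provably keeps coverage for every
  n ≥ 10; below 10 values the empirical minimum is used with a warning.
  Median and 95th-percentile suitability summaries, where no coverage
  contract applies, use the standard `type = 7` convention.
* **Youden threshold ties** break toward the lower (more sensitive)
  threshold; candidate thresholds are midpoints between consecutive distinct
  scores plus sentinels beyond the extremes.
* **cloglog calibration.** The constant $c$ is chosen so the mean presence
  linear predictor maps to suitability $\tau = 0.5$ (the familiar MaxEnt
  convention); $\tau$ is configurable.
* **Penalty selection.** The L1 penalty is chosen by held-out log-likelihood
  on an internal stratified 80/20 split over a data-driven lambda path, with
  a seed derived from the fit seed. Regularisation tuning is rarely
  documented in applied SDM work, so we fix a simple, reproducible rule.
* **Hinge knots.** 10 per predictor per direction, equally spaced strictly
  between the training minimum and maximum (7 + 7 + 21 + 70 + 70 = 175
  features for 7 predictors). Data-driven knot placement would be
  nondeterministic across folds; a fixed count is reproducible.
* **Seeds.** One master seed; each stage derives its own seed by hashing the
  stage name into [1, 2^31 − 2], so adding a stage never perturbs another
  stage's random stream, and identical configurations reproduce identical
  manifests (content-hashed outputs) bitwise.
* **Exact Shapley attribution.** With seven predictors, all $2^7 = 128$
  coalitions are enumerated and marginalised over a background sample, so
  local accuracy (base value + contributions = prediction) holds to floating
  point exactly; a Monte-Carlo permutation estimator is the fallback for
  larger predictor sets. Mean-|SHAP| effect classes use the cutoffs
  strong ≥ 0.05, moderate [0.02, 0.05), weak < 0.02, with both boundaries
  inclusive downward as stated.
* **Permutation importance** uses 10 permutations per predictor by default
  ("several times" is rarely quantified; 10 is cheap and stable).
* **Partial dependence** holds non-focal predictors at their reference
  **medians** by default. Mean conditioning is available by flag; method
  descriptions and figure captions in the applied literature disagree on
  this point, and the median is the more robust default for skewed land-use
  fractions.

## Scenario accounting

Projection applies the fitted ensemble to a perturbed stack and reports the
mean, median and 95th percentile of suitability over valid cells; areas
above the fixed thresholds 0.3 / 0.5 / 0.7; the P10 binary area; and the
net change (scenario − baseline, negative = net loss). Future binary maps
use the **baseline** ensemble P10 by default: the threshold is a property of
the calibration presences, which have no future analogue. Re-deriving the
threshold from scenario suitability at the (baseline) presence cells is
available via `p10 = "recompute"`, since published workflows are often
ambiguous about which was done. Change maps classify each cell as
stable-suitable / gain / loss / stable-unsuitable, and the accounting
identity area(gain) − area(loss) = net change holds exactly by construction
— it is asserted in the tests for every simulated scenario.

A pattern worth noting, because it looks paradoxical: the continuous mean
and median can **rise** while the P10 binary area **collapses**. This
happens whenever a scenario broadens mid-range suitability across the
domain while eroding the concentrated top tail below the (high) P10
threshold. The regression suite constructs exactly such a scenario —
a 5% high-suitability core (0.85–0.95) over a 0.03 matrix, moving to a
broadened 0.3–0.45 mid-range with the core eroded to ~0.5 — and asserts the
signature. It is a demonstrated possibility of threshold accounting, not a
universal law.

## GeoTIFF interchange

Rasters are exchanged as single-band, uncompressed, float32 GeoTIFFs with
nodata stored as NaN plus the GDAL nodata tag, georeferenced by a
pixel-scale/tie-point pair and a geographic-CRS GeoKey. The reader accepts
either byte order but refuses multi-band, compressed, non-float32 or
non-georeferenced files rather than guessing. This deliberately narrow
format is sufficient for suitability and predictor layers and round-trips
bitwise at float32 precision.

## Configuration and orchestration

`run_pipeline()` executes simulate/ingest → clean/thin → background → fit →
cross-validate → gate/ensemble → interpret → project → report from a single
nested configuration (R list or YAML overriding `default_pipeline_config()`),
logging per-stage counts and seeds and failing fast with stage-named errors.
Outputs are CSV tables (fold-level CV metrics, suitability summaries, area
accounting, importance and SHAP summaries, partial-dependence curves),
GeoTIFF surfaces (continuous, binary, change maps), a structured text
description of the ensemble, and a JSON manifest with an md5 content hash
per output. The package is a library: these functions, not a shell wrapper,
are its interface.

## Problem sizes

Defaults are sized so the complete workflow runs comfortably on a single
CPU: a 100 × 100 grid (10,000 cells), 300 presences and 600 background
cells, 500 trees, 175 MaxEnt-style features, 5-fold CV for both members,
exact Shapley on a 40-point evaluation sample against a 40-row background,
and four scenarios — about half a minute end to end. The unit-test fixtures
use 20–50 cell grids and run in seconds.

## Known limitations

* One taxon per run; multi-family comparisons are loops over configurations.
* Two member algorithms; the ensemble machinery is general but no other
  members are provided.
* No spatially blocked cross-validation; random stratified folds can be
  optimistic under strong spatial autocorrelation.
* No extrapolation diagnostics (MESS), no dispersal constraints, no
  sampling-bias models beyond suitability-proportional detection.
* The spherical datum introduces ~0.1–0.3% area error relative to an
  ellipsoid; consistent across all comparisons, so deltas are unaffected at
  the scales reported.
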