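---
title: "Methods: fine-scale topographic species distribution modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-scale topographic species distribution modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

At landscape scales, climate drives where plants grow; inside a single
square kilometre of desert dune, climate is effectively constant and
*microtopography* takes over: elevation above the water table, the
direction a slope faces, how steep it is, and whether the surface is
convex or concave. `toposdm` models the distribution of a plant over such
fine-scale terrain: it derives topographic predictors from a digital
elevation model (DEM), fits seven species distribution modelling (SDM)
algorithms to presence records on a 10 m analysis grid, compares them by
repeated cross-validated ROC analysis, and maps habitat suitability in
three bands. A virtual-species simulator with a known niche makes the
whole pipeline testable end to end by parameter recovery.

## Terrain predictors

Four predictors are derived from the DEM on the common 10 m grid
(`terrain_stack()`):

* **slope** (degrees) and **aspect** (degrees clockwise from north) from
  Horn's (1981) 3x3 finite-difference gradients — the algorithm used by
  mainstream GIS software, so results are reproducible elsewhere;
* **profile curvature** (per 100 m) from the Zevenbergen & Thorne (1987)
  quadratic surface fit: the curvature of the terrain along the direction
  of maximum slope. Sign convention, stated prominently because
  conventions differ between GIS packages: **positive = concave**
  (upward-curving along the slope line), negative = convex, exactly 0 on
  any plane;
* **dem**, the elevation itself (m).

Border cells and cells adjacent to nodata have no 3x3 neighbourhood and
become nodata. Flat cells have no defined aspect; they carry the sentinel
value -1 on the raw raster, and `terrain_stack()` masks them to nodata by
default because the models treat aspect as a numeric covariate. Aspect is
circular but is used as a raw linear covariate, matching common field
practice; a cosine/sine (northness/eastness) transform can be applied by
the user before stacking if preferred.

Collinearity among predictors is screened with variance inflation
factors (`vif_screen()`): VIF_j = 1/(1 - R^2_j) from regressing predictor
j on the others, iteratively dropping the largest VIF above the threshold
(default 10, the customary cut-off) until all pass. Ties are broken by
dropping the alphabetically later name so the procedure is deterministic.

## The seven models

All models are fitted through one front-end, `sdm_fit(X, y, method =
...)`, and score under one contract: *higher = more suitable*, variables
matched by name.

**Presence-only profile models** (trained on presence cells alone,
implemented in-package):

* **BIOCLIM** — the classic envelope. Per predictor, a candidate value is
  scored `2 * min(F, 1 - F)` with `F` the midpoint empirical CDF of the
  training values; the overall score is the minimum across predictors.
  1 at the per-variable medians, 0 outside any training min–max.
* **Domain** — Gower similarity. The range-standardized distance
  `d(A, B) = (1/Q) * sum_K |A_K - B_K| / range_K` is computed to every
  training site and the score is `S_A = max_j (1 - d(T_j, A))`: 1 at any
  training site, possibly negative far outside the training ranges (raw
  values are reported by default; habitat classification clamps at 0).
  Ranges come from the training presences, Domain's original definition;
  `range_K = 0` is an error rather than silently dropping a variable.
* **Mahalanobis** — `D^2 = (x - mu)' S^{-1} (x - mu)` with the presence
  mean and sample covariance (denominator n-1). The habitat score is the
  chi-square survival function of `D^2` on Q degrees of freedom, a
  probabilistic calibration that is monotone decreasing in `D^2`; raw
  `D^2` is also exposed. If the covariance condition number exceeds 1e10
  a ridge `lambda I` with `lambda = max_eigenvalue / 1e10` is added, with
  a warning — never silently.

**Presence/background models** (trained on labelled 0/1 rows, backed by
the standard implementations):

* **GLM** via `stats::glm`. The default family is **gaussian** — an
  identity-link linear-probability fit of the 0/1 labels. That is a
  deliberate fidelity choice: this pipeline's reference protocol fits the
  gaussian family, and the package defaults to it while exposing
  `family = "binomial"` (logistic regression) as the statistically
  conventional alternative. Gaussian-family scores can leave [0, 1];
  rank-based AUC is unaffected, and maps are min–max rescaled before
  habitat classification.
* **GAM** via `mgcv::gam`, one penalized thin-plate smoother per
  predictor (basis dimension 10, REML smoothness selection), binomial by
  default; predictors with fewer than 10 unique values fall back to
  linear terms with a warning.
* **Random forest** via `randomForest`, classification mode (labels as a
  factor), `ntree = 500`, `mtry = 10`; when fewer predictors are
  available `mtry` is clamped with a warning rather than erroring — with
  the standard four terrain predictors the effective `mtry` is 4. The
  score is the presence-class vote fraction.
* **SVM** via `e1071::svm`, Gaussian (radial) kernel, soft margin
  (`cost = 1`), kernel width `gamma = 1/Q` on internally standardized
  predictors. The score is the signed decision value, oriented so larger
  means more suitable; only support vectors influence it.

## Evaluation protocol

`repeated_evaluation()` mirrors a repeated random-background design: for
each of `n_runs = 10` runs it draws a fresh uniform background sample of
`n_background = 100` cells (disjoint from presences), partitions
presences + background into `k = 5` folds — stratified by label, so each
fold preserves the presence:background ratio; plain random folds are
available — trains on k-1 folds and scores the held-out fold. Profile
models see only the training-fold presences; supervised models see
training-fold presences and background. AUC (Mann–Whitney pair count,
ties one half) and optimal-threshold rates are computed on each held-out
fold and averaged within the run. How the k-fold split composes with the
repeated runs is genuinely open in such protocols; fold-averaging within
run is the most common composition and is what the package does,
deterministically under one master seed (per-run, per-model seeds are
derived from it by fixed offsets, so adding a model never shifts the
randomness of the others). A failed model-run is recorded as `NA` with
its reason, never silently dropped.

Threshold selection (`best_threshold()`) scans midpoints between
consecutive distinct scores plus sentinels beyond both ends, breaking
criterion ties toward the lowest threshold (the more sensitive
classifier). Two criteria are provided because the common "maximize
TPR + TNR" phrase is ambiguous when TNR is printed with the
false-positive-rate formula `C/(C+D)`: `"youden"` (default) maximizes
TPR + specificity - 1, the standard reading; `"paper_literal"` maximizes
TPR + C/(C+D) for comparability with tables that use the literal
formula. AUCs are rated excellent (> 0.9), fair (0.7–0.9) or poor
(< 0.7), boundary values falling to the lower band as the strict
inequalities state.

## Suitability maps, habitat bands, response curves

`predict_map()` scores every valid cell and propagates nodata; scorers
that are not probabilities (gaussian GLM, raw Domain, SVM decision
values) are min–max rescaled to [0, 1] before classification, and the
rescaling is part of the map's provenance. `classify_shi()` applies the
three-band suitable-habitat-index classification — unsuitable (SHI <=
0.3), low suitable (0.3 < SHI <= 0.5), suitable (SHI > 0.5), boundaries
exactly as written — and `area_summary()` converts cell counts to areas
(count x cellsize^2) and percentages that sum to 100 over valid cells.
An alternative "minimum training presence" thresholding mode was
considered (classifying relative to the lowest presence score) but the
fixed 0.3/0.5 bands are the operative definition; users can pass custom
thresholds.

`response_curve()` sweeps one predictor across its observed range (or an
explicit `from`/`to`) with the others held fixed, the "driven factor"
analysis. Two fixing strategies exist: landscape medians (default) and
presence means. For a *narrow-niche* species the presence-mean strategy
is the informative one — fixing elevation at the landscape median can
place every sweep point outside the species' envelope and flatten a
profile model's curve to zero — so the recovery analyses in this package
use `fixing = "presence_mean"`. `curve_argmax()` reports the peak
location; across a plateau of tied maxima (piecewise-constant learners
such as random forests) it returns the plateau midpoint.

## The virtual species generator

`simulate_scenario()` builds the package's reference study design: a
100 x 100 grid of 10 m cells (1 km^2), elevations spanning exactly
1009–1016 m, and a virtual shrub with 67 presence cells and 100
background cells — sizes chosen so evaluation tables have the shape of a
real fine-scale dune study.

The DEM comes from spectral synthesis: complex white noise shaped by a
power-law amplitude spectrum `f^(-roughness/2)` and inverted by FFT,
giving a smooth, spatially autocorrelated surface. Two post-transforms
matter:

* **Hypsometry.** The raw spectral field has a bell-shaped elevation
  histogram: almost no area sits near the band minimum, so a species
  whose optimum (1010 m) lies 1 m above the minimum would occupy a
  vanishing sliver and its sampled presences would be biased upslope by
  ~0.5–0.9 m. Real dune plains spread area much more evenly across their
  elevation band. The generator therefore applies a monotone
  histogram-flattening (rank) transform by default before the affine
  rescale; being monotone, it preserves smoothness and spatial
  autocorrelation. `hypsometry = "gaussian"` keeps the raw field.
* **Roughness.** The scenario default exponent is 2 so that slopes reach
  roughly 15–17 degrees and the edge of the species' slope plateau is
  observable in the data; the generic DEM default (3) gives smoother
  terrain with slopes of only a few degrees.

The niche (`niche_spec()`) multiplies four responses, limiting-factor
style, each mapping to [0, 1]:

| predictor | form | default | why |
|---|---|---|---|
| elevation | Gaussian | opt 1010 m, sd 0.5 m | steep, unimodal elevation response of a dune shrub |
| aspect | cosine southness, power | 180 deg, power 2 | clear south-facing preference; power 1 spreads half the mass over a 180-degree arc, too diffuse to call "south-facing" |
| slope | logistic plateau-decay | half-point 20 deg, 0.5/deg | suitable on gentle slopes up to ~20 deg, declining beyond |
| profile | Gaussian | opt 0, sd 0.5 per 100 m | flats and straight slopes preferred over sharp breaks |

The product is scaled so the *expected* number of occupied cells equals
the presence target (the expectation is monotone in the scale because
cells saturate at probability 1, so the calibration is a root-find), one
Bernoulli draw per cell gives occurrences, and the draw is repeated over
derived sub-seeds until the deduplicated count matches the target
exactly. Everything is byte-reproducible from the master seed.

What the generator does **not** emulate: dispersal limitation, biotic
interactions, temporal dynamics, observation bias, GPS error, and any
predictor the models do not see (e.g. groundwater depth). Passing
recovery tests therefore show the pipeline can find a niche that is
expressible in its own predictors — they do not certify performance on
real data, where the niche is partly driven by unobserved factors and
occurrence records carry sampling structure.

## Numerical choices and degenerate inputs

* Cells are half-open intervals `[x0, x0 + cellsize)`, so every point
  maps to exactly one cell; boundary points of the study polygon count
  inside (even–odd rule).
* ESRI ASCII rasters accept both `xllcorner` and `xllcenter` headers and
  write `xllcorner`; nodata default -9999. GeoTIFF is not supported in
  this build (no GeoTIFF-capable library is linked); the `format`
  argument errors informatively.
* Aggregation to coarser grids uses the block mean by default (min/max
  available for sensitivity checks); trailing partial blocks use the
  cells available.
* Constant predictors: BIOCLIM keeps them (the envelope degenerates to a
  point), Domain refuses them (zero range), Mahalanobis ridges the
  covariance, GLM drops aliased columns with a warning.
* Single-class labels are an error for every supervised learner and for
  all confusion/ROC computations.
* All stochastic steps (terrain simulation, occurrence draws, background
  samples, folds, forests) save and restore the caller's RNG state, so
  library calls never perturb user scripts.

## Problem sizes

The reference analyses in the package run at the design scale the
methods are meant for: a 10^4-cell grid, 67 presences, 100 background
cells, 5 folds, 10 evaluation runs (20 for the paired model
comparisons). These sizes keep every analysis exactly reproducible in a
few minutes on a single core while leaving all statistics at their
intended sample sizes.

## Limitations

Aspect enters linearly despite being circular; the gaussian-family GLM
is a linear-probability model retained for protocol fidelity; no
spatially blocked cross-validation is offered (random folds can be
optimistic under strong spatial autocorrelation); ensemble/consensus
prediction is out of scope; suitability maps are per-cell with no
between-cell interpolation.
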