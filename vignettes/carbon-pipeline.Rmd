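---
title: "Methods: forest carbon accounting across paired resolutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forest carbon accounting across paired resolutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbonscape)
```

## The problem

Regional forest carbon stock in semi-arid northern China is dominated by
shrubland: shrub carbon density is low (single-digit t/ha) but shrub cover
is vast, so small per-pixel errors integrate into large storage errors.
Two practical obstacles shape the pipeline implemented here. First, field
plots are sparse (on the order of a hundred), so pixelwise models must be
simple and screened predictors must be few. Second, the imagery that
supports fine thematic detail (a 10 m, 6-band layout) is not the imagery
with the long historical archive (a 30 m, 3-band layout); estimating
*change* therefore requires a model on the coarse sensor, trained somehow
from the better contemporary evidence.

## Plot-level carbon: allometry

Each surveyed plot is converted to carbon density (t/ha) by summing
individuals. Trees use organ-wise power laws `W = a·(D²H)^b` with DBH in
cm, height in m and dry mass in kg — the unit convention under which the
shipped coefficients give plausible stem masses (a 20 cm / 10 m *Populus*
trunk evaluates to 65.46 kg). Organ masses (trunk, branch, leaf, root) are
summed, multiplied by a species carbon fraction (0.41–0.50), accumulated
over the plot (0.04 ha for tree plots, 0.01 ha for shrub plots) and
divided by the area. Shrubs use whole-plant models on crown volume
(`W = a·V^b`) or on the height-crown-width product
(`W = c₀ + c₁(HM) + c₂(HM)²`). The herb layer comes from 1 m² quadrat dry
masses: mean over quadrats of (above + below ground mass) × carbon
fraction, in kg C/m², which converts to t/ha by the factor 10.

Three registry choices were genuinely open and are package decisions:

* **Crown volume.** The source registry never defines `V`; we use the
  ellipsoid `V = (π/6)·M²·H` and make the convention a function argument,
  so any other shape factor can be substituted.
* **Corrupted shrub coefficients.** The printed shrub equations are
  typographically impossible (an exponent of 1060.59; a polynomial with a
  missing operator). The shipped shrub entries are therefore *synthetic
  placeholders* — `whole_power` with `b = 1.06`, `whole_poly` with
  coefficients `(0.061, 0.2854, 0.0516)` — flagged as non-published values
  and meant to be overridden from a YAML registry when measured equations
  are available.
* **Herb carbon fraction.** The regional guideline value is not printed;
  the default 0.45 is configurable everywhere it is used.

Species not present in the registry either raise an error naming the label
or, with `fallback = TRUE`, substitute a similar species' model — the same
substitution convention inventories use for unmeasured species.

## Vegetation indices and predictor screening

Indices are band arithmetic on reflectance stacks; both sensor layouts
resolve the generic `NIR/red/green/blue` roles to their own bands. Three
registry details are deliberate: SAVI's soil factor defaults to `L = 0.5`
(configurable) because the printed formula writes `+ L` without a value;
the coarse layout's SAVI is the NIR/red form (the printed reference to a
panchromatic band is treated as a typo); and NDWI/EVI/gCI — named in the
source's correlation table but never defined there — use their standard
published definitions (on the 3-band layout EVI falls back to the two-band
EVI2 form, since no blue band exists). Zero-denominator pixels are masked,
never infinite.

Screening is two-stage. Candidates are ranked by `|r|` (Pearson) against
observed density and selected at a threshold, default 0.5. The source text
says "coefficient of determination greater than 0.5" while its own table
retains indices with `r ≈ 0.36–0.49`; we read the rule as applying to
`|r|`, keep it configurable, and add a `top_k` fallback so a model always
exists. Collinearity is then removed iteratively: the worst
`VIF = 1/(1−R²ⱼ)` above 10 is dropped (later-ranked column first on ties,
exact collinearity first of all) and VIFs are recomputed — worst-first
removal is standard practice and deterministic, unlike single-pass
deletion. Rows with any missing value are dropped listwise before either
stage.

## Density models and their evaluation

Three families are supported with fixed protocol hyperparameters: random
forest (100 trees, maximum depth 5, minimum node size to split 3, all
predictors tried per split, RNG state 42), a single regression tree
(depth 4, minimum split 3, no cost-complexity pruning, RNG state 42), and
ordinary least squares. Data are split 7:3 by simple random sampling with
a fixed seed; the training share is `⌈0.7n⌉`. Evaluation reports R²
(1 − SSE/SST), RMSE, rRMSE, MAE and MBE with the sign convention
observed − predicted, so positive bias means underprediction. The printed
form of rRMSE (square root of MSE/ȳ) is dimensionally inconsistent — its
value would depend on the measurement unit — so the package defines
rRMSE = RMSE/ȳ and keeps the printed form behind
`evaluate_metrics(..., rrmse_form = "printed")` for comparison.

Maps floor negative predictions at zero (densities are physical) and
report how many pixels were floored; metric computations use the raw
predictions, so flooring never flatters accuracy statistics.

## Cross-resolution transfer

"Approach 1" regresses the ~96 plot densities directly on 30 m indices.
"Approach 2" first fits per-class models at 10 m, mosaics the five class
maps (masks must partition the forest; overlaps are an error), aggregates
the mosaic to the exactly nested 30 m grid by 3×3 block means over forest
children (recording each cell's forest fraction), and then uses those
reference cells — tens of thousands of them — as training targets for the
30 m model. Training and prediction are restricted to cells with forest
fraction ≥ 0.5, limiting the mixed-pixel dilution that coarse sensors
suffer at stand edges; the threshold is an argument. Mean aggregation is
the default resampling operator; nearest-neighbour is available behind a
flag. The fraction-weighted 30 m total equals the 10 m total identically
(it is the same sum regrouped), which the tests assert to 1e-6 relative as
a guard on the implementation.

Discrepancy between two maps is `|est − ref| / ref` per pixel, classed
minor (< 30 %), moderate (30–60 %) or substantial (> 60 %). The source's
"between 30 and 60 %" is ambiguous at the endpoints; both endpoints are
classed moderate (closed interval), and zero-reference pixels are excluded
and counted rather than producing infinities.

For temporal change the 2023 whole-forest total is compared against the
2013 coarse-sensor estimate; the shipped printed-totals table reproduces
the reported +12.21 Mt (+89.02 %) only under that pairing (fine-sensor
2023 total over coarse-sensor 2013 total), which is therefore the default
baseline convention in the worked examples.

## Land cover and geodetector

The land-use step is Gaussian maximum likelihood: per class a sample mean
and covariance (ridge `1e-8·trace/n_bands` added only if the covariance is
singular, and reported), classification by argmax of log-likelihood plus
log prior. Priors default to equal because the source states none. Exact
score ties go to the lowest class index; scores are rounded at the ninth
decimal first so that last-bit floating noise cannot hide a designed tie.
Accuracy is summarized by overall accuracy (trace/n) and Cohen's kappa
`(p_o − p_e)/(1 − p_e)`.

The geodetector quantifies stratified spatial heterogeneity. The source
names the method without printing a formula, so the canonical definition
is adopted: `q = 1 − Σ n_h σ²_h / (n σ²)` with population variances;
strata with fewer than two observations are excluded and reported, and a
single remaining stratum yields `q = 0` with a flag. Interactions use the
cross-classification of two stratifications and the five standard
categories (nonlinear weaken, univariate weaken, bivariate enhance,
independent, nonlinear enhance), with a small tolerance deciding
"independent" since exact equality is a measure-zero event in floating
point. Significance testing is omitted: the analysis reproduced here
reports no p-values. Continuous covariates are discretized by quantiles
(balanced counts) or equal intervals; empty classes are merged and
reported. Published q values for the real covariate rasters are *not*
reproduction targets — those rasters are not available — the module
reproduces the analysis form and is validated on constructed strata
instead.

## What the synthetic scene emulates — and what it does not

The generator is first-class, tested code, and its defaults are the study
conditions: a 10 m grid divisible by 3 (so the 30 m grid nests exactly),
five forest classes partitioning a forest extent that covers 60 % of the
scene, per-class density means and ranges equal to the surveyed plot
statistics (e.g. *Populus* 32.31 t/ha in 4.04–70.70; shrub 9.13 in
3.36–15.69), the 20/18/20/18/20 plot layout (96 plots), and a target
NDVI–density correlation of 0.9 — the magnitude of the stronger
index-density correlations reported for this landscape.

Construction, all seeded from one root seed via drawn stage seeds:

* **Latent fields.** Gaussian-smoothed white noise (smoothing radius 6
  pixels, exact edge-renormalized convolution), rescaled per class to
  `mean ± (max−min)/6` and clipped to `[min, max]` — the simplest field
  with controllable spatial autocorrelation.
* **Reflectance.** Vegetated pixels follow a saturating Michaelis response
  `g = d/(d + 50)`: red decreases and NIR increases in `g`, reproducing
  the NDVI saturation that limits optical carbon mapping at high density.
  The half-saturation of 50 t/ha keeps the noiseless NDVI–density
  correlation ceiling near 0.98, so the calibration target is attainable;
  tree and shrub canopies share the red/NIR response (a pooled NDVI stays
  informative) while shrub is separable through its brighter green/red-edge
  soil background. Four non-forest spectra (cropland, grassland, water,
  bare) make the six-class legend learnable. Band noise has a base sensor
  component (default sd 0.005 reflectance units) plus an extra component
  on the signal bands whose scale is bisected until corr(NDVI, density)
  over forest pixels equals the target; the 30 m stack is the exact 3×3
  block mean of the 10 m bands plus independent sensor noise, and the
  noise-free 30 m stack is retained for invariance checks.
* **Plots.** Centers are sampled within each class mask; the local true
  density (default ±10 % relative noise — the plot-to-imagery mismatch is
  not published, so this is a package choice) is split into a small herb
  component and a woody target, and the class's allometric model is
  inverted for a common `D²H` (trees) or crown volume (shrubs) so the
  computed plot density reproduces the target. With zero noise the
  round-trip through the allometry is exact to solver tolerance.
* **Factor strata.** A mixing construction (rank slices vs random labels,
  mixing fraction bisected on the realized ANOVA between/total share)
  produces stratifications with a requested explained-variance share; the
  realized share is computed from plain group sums, independent of the
  geodetector implementation it validates. A share of exactly 1 is
  unattainable for continuous values with few strata; the construction
  then returns pure rank slices and warns.

The scene does **not** emulate: radiative transfer, atmosphere, terrain
illumination, clouds or shadows; sensor point-spread functions (the 30 m
pixel is an exact block mean); phenology or multi-date consistency beyond
re-running the generator; spatially correlated sensor noise; or plot
geolocation error. Passing tests therefore demonstrate that the *methods*
are implemented correctly and behave as designed under controlled signal
and noise — not that real Ordos accuracy figures would be reproduced.

## Numerical and protocol choices

* Pixel-is-area, north-up grids; point extraction is containment-based
  with half-open pixels, so points on a shared edge belong to exactly one
  pixel.
* Correlation screening ties break by registry order; VIF removal prefers
  the later-ranked column; both make selection deterministic.
* The geodetector uses population (not sample) variances, making `q`
  exactly the between/total sum-of-squares share.
* Problem sizes in the shipped tests and reproduction script: 150×150 and
  300×300 10 m scenes (22,500–90,000 pixels, 13,500–54,000 of them
  forest), 96 plots, 20 replicate scenes for the approach comparison —
  sizes at which every stochastic check is stable across seeds while the
  whole suite runs in well under a minute.
* Rasters travel in memory as plain matrices with an affine origin;
  single-band grids serialize to ESRI ASCII grid text (nodata −9999
  continuous, 0 categorical). No GeoTIFF dependency is required anywhere
  in the pipeline.

## Known limitations

* The shipped shrub allometry coefficients are placeholders (see above);
  absolute shrub masses are only as good as the registry supplied.
* Soil carbon, deadwood and litter pools are out of scope, as is
  uncertainty propagation through the allometric coefficients.
* MLR on saturating indices under-predicts the highest densities; the
  cross-resolution reference transfer inherits whatever bias the 10 m
  mosaic has — it matches the *reference*, not ground truth, which is
  exactly the trade-off the discrepancy report is meant to expose.
* Inputs must share a CRS; no reprojection is performed.
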