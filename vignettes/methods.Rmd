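---
title: "Habitat models from interpolated singlebeam bathymetry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat models from interpolated singlebeam bathymetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Full-coverage multibeam (MBES) bathymetry is the gold standard input for
demersal fish species distribution models (SDMs), but most shelf seafloor has
only been surveyed with singlebeam echo-sounders (SBES), which measure a
single depth directly beneath the vessel along widely spaced transects.
Turning SBES lines into a continuous digital elevation model (DEM) requires
interpolation, and the choice of interpolator, the quality of the resulting
terrain derivatives, and the knock-on effect on habitat models are all
empirical questions. `bathysdm` implements that whole chain — sounding QC,
interpolation with explicit model selection, multi-scale terrain derivatives,
surface agreement diagnostics, and random-forest presence/absence models
compared by cross-validated AUC — together with a synthetic-data module that
plays the role of the field data, so every stage can be verified at desk
scale.

This vignette records the models, the defaults and why they were chosen, the
numerical decisions, and the limits of what the synthetic experiments can
show.

## The synthetic shelf

`seafloor_scenario()` describes depth (metres, positive down) as

> trend + anisotropic Gaussian random field + nugget noise,

where the trend is an across-shore ramp (default 20 m at the shoreward edge
rising to 130 m over 5 km, i.e. a gradient of 0.022 m/m — a gentle shelf of
roughly 1 degree) and the random field has Gaussian covariance

$$C(h) = \sigma^2 \exp\!\big(-3 (h/a)^2\big),$$

parameterized so that `a` is the *effective range*: the distance at which the
semivariogram reaches 95% of the sill. Geometric anisotropy rotates lags into
(major, minor) axes and stretches the minor component by `1/ratio`; the
default major axis runs parallel to the coast (90 degrees from north) with
ratio 0.5, mirroring the common situation where depth changes much faster
across-shore than alongshore. The default effective range of 600 m sits in
the 400–750 m window typical for shelf relief at this scale, and the default
sill of 4 m² gives a seafloor with a few metres of relief on top of the ramp.

The field is simulated by circulant embedding on a doubled grid — exact for a
stationary covariance up to clipping of small negative embedding eigenvalues,
which the Gaussian covariance can produce; the generator warns when the
clipped mass is material. A Monte-Carlo test (20 seeds, ~10⁴ cells) confirms
the realized detrended variance matches the sill.

`sample_survey()` emulates the acquisition: shore-parallel transects at
500 m spacing (edges inclusive), one sounding every 40 m along track,
boustrophedon steaming for coherent timestamps, and a recorded raw depth
equal to the bilinear DEM depth plus a sinusoidal tide (default amplitude
0.8 m, period 12.42 h — a semi-diurnal lunar constituent), Gaussian noise
(default sd 0.2 m) and rare spikes of ±25 m. The true spike labels travel
with the data so the despiker can be scored. Tides are a single sinusoid on
purpose: that is sufficient to exercise the correction path, and nothing
downstream depends on harmonic structure.

Stations are placed uniformly with a minimum separation (defaults n = 500,
200 m) by rejection sampling; the field sampling design they emulate is not
prescribed any further, so uniform is the neutral choice.

## Sounding QC

The QC chain is `block_average` → `tide_correct` → `despike`, each appending
to a provenance log. Block averaging pools `k` consecutive records within a
transect into their mean (the depth-domain analogue of averaging raw pings;
a trailing group is kept when it has at least `k/2` members). Tide correction
subtracts the linearly interpolated tide height less the chart-datum offset
and is exactly invertible. The synthetic survey already emits one sounding
per 40 m, so the pipeline default is `k = 1`; the order of averaging versus
tide correction is switchable and immaterial for a tide that is effectively
constant over a block.

Despiking replaces the manual editing step used in practice with a
reproducible filter: a record is dropped when it deviates from the 5-point
running median by more than 6 running noise scales, the scale being the
running median absolute first difference divided by √2 over a window five
times wider (floored at 0.01 m). The first-difference scale matters: on a
smooth seabed the running median coincides with the centre value over
locally monotone stretches, so a MAD of the median residuals collapses to
zero and would reject ordinary noise at the several-percent level, while the
increment-based estimator recovers the noise sd robustly regardless of
smooth terrain. Measured on synthetic surveys with 1% injected ±25 m spikes,
the filter removes 100% of spikes with ~0.01% false removals. It is
idempotent, and also drops non-positive depths.

`summarize_soundings()` reports n, min, max, mean and the adjusted
Fisher–Pearson skewness coefficient, flagging |skewness| > 1 as
"transformation advised" — the usual screening rule before geostatistical
analysis. Constant samples are reported as skewness 0 with a zero-variance
flag rather than NaN.

## Variograms

The empirical semivariogram is the classical Matheron estimator binned by
lag, omnidirectionally and in compass sectors (default 0/45/90/135 ± 22.5
degrees). Two practical decisions:

* **Residual variograms.** `detrend_degree` removes a global polynomial
  trend before binning. With the across-shore ramp left in, the sample
  variogram grows without bound, the weighted fit runs into its bounds, and
  the fitted nugget collapses to zero — which then makes the Gaussian-model
  kriging systems numerically singular. Fitting the variogram of degree-1
  residuals is the standard companion to universal kriging (the kriging
  system carries the trend) and is the pipeline default.
* **Bounded fits.** The Gaussian model is fitted by weighted least squares
  with Cressie weights `N(h)/γ(h)²`, from several starts, with the range
  bounded by 1.5× the maximum lag and the sill by 3× the empirical ceiling:
  neither is identifiable beyond the data support, and unbounded fits
  occasionally chase a slowly-creeping tail to absurd parameters.

Anisotropy is estimated from the directional variograms with the nugget and
sill pinned at their omnidirectional values and only the range free per
direction — directional bins hold far fewer pairs and a fully free fit is
poorly identified. The major axis is the direction of maximal fitted range;
the ratio is minor/major, clipped to (0, 1]. One further identifiability
guard: a directional range is never taken below half the first populated
lag. This matters for transect surveys, where the across-track sector has no
pairs below the 500 m line spacing; without the bound, the optimizer returns
an arbitrarily small range (every candidate below the first lag fits the
at-sill bins equally well) and the resulting over-stretched anisotropy
visibly degrades kriging.

On noise-free Gaussian-field samples (2000 points, 10 seeds) the fit
recovers the range within ±30%, the sill within ±25%, and a true ratio of
0.5 within [0.35, 0.65] in aggregate; on exact model-generated bins it
recovers all three parameters to 10⁻³ relative.

## Interpolators

All interpolators share a local-neighbourhood design (brute-force k-nearest
neighbours, ties broken by point index), which keeps leave-one-out
cross-validation of thousands of points and million-cell grid predictions
tractable without a global solve.

* **IDW** with weights `d^(-p)` over the k nearest points and an exact-hit
  rule at 10⁻⁹ m. Predictions are convex combinations, hence bounded by the
  neighbourhood extremes, and tend to the nearest-neighbour value as p grows.
* **RBF** solves the local augmented system `[Φ P; Pᵀ 0]` with a linear
  polynomial part (so planes are reproduced exactly) for two bases: the
  multiquadric and the completely regularized spline
  `φ(r) = -(\ln x + E_1(x) + γ_E)` with `x = (δ r / 2)²` (the spline-with-
  tension radial series; `E_1` is the exponential integral, `γ_E` Euler's
  constant). The multiquadric is taken with a negative sign, which leaves an
  exact interpolant unchanged but makes the basis conditionally positive
  definite under the linear side conditions — the sign on which the
  "robustness" smoothing ridge depends. Robustness is implemented as a
  dimensionless ridge scaled by the mean |φ| of the local system: the ridge
  then means the same amount of smoothing at any site scale, LOOCV selects
  zero robustness on exact data and positive robustness on noisy data, and
  growing the ridge smoothly approaches a local linear regression rather
  than destabilizing the solve. `optimize_rbf()` grid-searches (δ,
  robustness) by LOOCV RMSE with ties resolved to the smallest δ then
  smallest robustness.
* **Kriging** (ordinary and universal with degree-1/2 local trend) solves
  the semivariogram-form augmented system per cell with locally
  centred/scaled trend coordinates, a 10⁻¹⁰ diagonal jitter (the Gaussian
  model is notoriously ill-conditioned), pseudo-inverse fallback for
  singular systems, and anisotropy applied by rotating/scaling lags before
  evaluating γ. The kriging variance is `λᵀγ₀ + μᵀf₀`, clamped at zero
  before the square root.

Model selection follows the field's convention: within the IDW and RBF
families the LOOCV RMSE; within kriging the |ASE − RMSE| calibration score
(average kriging standard error versus realized error); across families the
lowest RMSE wins. The LOOCV reuses the variogram fitted once on all data —
per-fold refits would change the estimand and cost two orders of magnitude
more.

On the default synthetic survey the selection reproduces the qualitative
field result: universal kriging with first-degree detrending attains the
lowest mean LOOCV RMSE over ten seeds, the optimized RBF sits between, and
IDW is last — and the kriging standard errors are calibrated
(|ASE − RMSE|/RMSE well under 0.25) when the data come from the variogram
used to krige.

## Terrain derivatives

`build_stack()` smooths the DEM once at native resolution with a normalized
5×5 Gaussian kernel (σ = 1 cell — the kernel width is not dictated by
anything upstream, and 1 cell is the common default), resamples bilinearly
to each target resolution, and computes eight derivatives per resolution
from 3×3 windows: Horn slope, northness and eastness (cos/sin of the
downslope compass direction, with NS = WE = 0 at numerically flat cells so
SDM feature matrices stay complete), standard deviation of depth (sample,
n−1, computed in centred two-pass form — the sum-of-squares shortcut loses
~8 digits at typical shelf depths), TRI, TPI, roughness, and mean curvature
(−(a+b) of the least-squares quadratic fit to the window on elevation
= −depth, so depressions are negative). Depth itself enters once, at native
resolution. All derivatives are computed on elevation where orientation
matters and are invariant to a constant depth shift.

The resolution ladder defaults to multipliers {1, 3, 5, 8} of the native
cell — for the 25 m synthetic native grid: 25/75/125/200 m, the same 1:8
span as a 3–25 m ladder on 3 m field data. On rough synthetic seafloors the
stack reproduces the expected scale behaviour: mean slope decreases, and
mean SD/TRI/roughness increase, monotonically from the finest to the
coarsest resolution.

## Surface agreement

`distance_to_track()` gives exact point-to-segment distances per cell;
`band_compare()` computes Pearson r (with its t-test p-value) and the OLS
regression of reference on predicted (slope, intercept, R²) within half-open
distance bands (lower, upper] — half-open so a 100.0 m pixel falls in the
first band and the bands tile the line without gaps. Defaults are the
0–100/101–200/201–300/301–400 m bands. Regressing reference on predicted is
a documented convention, not a claim. Two caveats are deliberate: p-values
ignore spatial autocorrelation (no effective-sample-size correction), so
they are optimistic; and with perfectly regular 500 m transects no cell is
farther than 250 m from a line, so the outer bands only populate when the
survey has gaps — the package's experiments emulate one lost line for the
band analysis, which is also what irregular real coverage looks like.

On the synthetic shelf the band R² declines monotonically from the
near-track band (>0.99) to the 301–400 m band, seed after seed — the
hallmark pattern of interpolation error growing away from the data.

## Species models

`simulate_species()` draws Bernoulli occurrence with

$$\operatorname{logit} p = \beta_0 - \beta_d \left(\frac{\text{depth} -
d_{opt}}{d_{tol}}\right)^2 + \sum_j \beta_j \, z_j,$$

a unimodal depth response plus optional linear responses to standardized
terrain layers. When a target prevalence is set, the intercept is calibrated
by root-finding on the expected prevalence (matched within 0.02). The two
stock species bracket the interesting regime: a *depth specialist*
(β_d = 6, optimum at the deep end, prevalence 0.3) that a terrain-based
model should capture, and a *no-signal generalist* (all betas 0, prevalence
0.7) that it should not — prevalences chosen to mirror the common field
situation of specialists being scarce and generalists ubiquitous.

`fit_rf()` fits a 500-tree random-forest classifier (mtry = ⌊√p⌋, no class
weights — conventional defaults) on a stratified 70/30 split and reports the
holdout AUC and residuals (observed − predicted probability, positive =
underprediction); `cv_auc()` runs stratified 5-fold cross-validation over
all stations (the holdout experiment is kept separate rather than nesting
the folds inside the 70% — the simpler design, since nothing downstream
needs nested estimates). Stratification is not optional: with prevalences
from 0.3 to 0.7 at a few hundred stations, unstratified folds can lose a
class. Sources are compared by a two-sided Welch t-test on fold AUCs —
Welch rather than paired, because the folds of independently split sources
are not natural pairs.

Variable importance is permutation importance on the holdout (mean AUC drop
over 10 permutations), chosen over impurity importance because the
multi-scale terrain features are strongly correlated and impurity measures
are biased in exactly that setting; rankings quoted anywhere in this package
depend on that choice. Partial dependence clamps one feature across an
equally spaced quantile grid (2.5–97.5%) and averages the predicted
probability over the training data. `predict_surface()` evaluates the model
at every native cell.

The synthetic end-to-end pattern matches the field study's: the depth
specialist is modelled with mean 5-fold AUC ≳ 0.9 from the reference grid
*and* from the kriged SBES grid with no significant AUC difference (Welch
p > 0.05 in the large majority of seeds); the generalist stays at chance
(AUC ≈ 0.5, below the 0.7 usefulness threshold); depth ranks first in
importance for the specialist; and its probability surface is higher in the
deepest quartile than the shallowest.

## Pipeline, determinism, problem sizes

`run_experiment()` composes the stages from one (YAML-overridable)
configuration, writes every artifact as text (ESRI ASCII rasters, CSV
tables, WKT tracks, a JSON manifest with file hashes), and caches each stage
keyed by the hash of the configuration subset it depends on, so an unchanged
rerun reloads bit-identical results. Every stochastic step takes a named
seed derived from the master seed; repeated runs are bit-identical.

The package's own experiments and tests run on a 4 × 2.5 km sub-extent of
the default 35 × 5 km shelf at a 25 m cell (≈ 600 soundings per survey, 300
stations, 32-point neighbourhoods, two-resolution stacks) — small enough
that the full property suite, with its ten-seed aggregates, completes in a
few minutes, while keeping every structural feature of the full-scale
scenario (multiple transects, anisotropy at survey scale, tide and spikes).
Neighbourhood sizes scale with the point counts; at full survey density the
50–150-point neighbourhoods of field practice are the counterpart of the 32
used at desk scale.

## What the synthetic experiments do not show

The generator produces a stationary Gaussian field on a ramp. Real shelf
seafloor has reefs, scarps, sand waves and other non-Gaussian, non-stationary
micro-relief; real SBES data have beam-width and sound-speed artefacts;
real species respond to more than depth and terrain, and their detection is
imperfect. Passing the synthetic suite therefore demonstrates that the
*machinery* is correct and that the method ordering holds under the stated
statistical structure — not that any particular field dataset will reproduce
those orderings, and not that the absolute RMSEs or AUCs transfer. The
surface-agreement p-values are optimistic (spatial autocorrelation), and
probability surfaces inherit interpolation artefacts near track gaps, which
is precisely the effect the band analysis is designed to expose.
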