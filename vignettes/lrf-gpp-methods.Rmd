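---
title: "Modelling gross primary production with an asymptotic light response function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gross primary production with an asymptotic light response function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrfgpp)
```

## The model and its assumptions

Ecosystem-level carbon uptake does not increase linearly with light.
At daily resolution the relationship between gross primary production
(GPP) and incoming photosynthetically active radiation (PAR) is
asymptotic, and `lrfgpp` represents it with the Mitscherlich light
response function

$$\mathrm{GPP} = F_\mathrm{opt}\left(1 - e^{-\alpha\,\mathrm{PAR}/F_\mathrm{opt}}\right),$$

with photosynthetic capacity $F_\mathrm{opt}$ (g C m⁻² day⁻¹, the uptake
level at light saturation) and quantum efficiency $\alpha$
(g C day⁻¹ W⁻¹, the initial slope). GPP is reported with a positive sign
for uptake throughout; the micrometeorological convention that writes
uptake as a negative flux is dropped because every budget and evaluation
uses positive GPP. PAR is taken as 46% of downwelling shortwave
radiation.

The central assumptions are:

* **Capacity and efficiency track greenness.** $F_\mathrm{opt}$ and
  $\alpha$ are smooth, saturating functions of NDVI, represented by the
  three-parameter logistic $a_{max}/(1+e^{-k(x-x_{mid})})$ with maximum,
  steepness and midpoint. (The logistic is implemented in this standard
  form; the maximum/steepness/midpoint reading is what the parameters
  mean everywhere in the package.) Both curves are biome-specific, with
  biomes defined by merging the sixteen IGBP land-cover classes to eight
  (shrublands and woody savannahs into savannahs, wetlands into
  grasslands, mosaics into croplands; urban, snow/ice and barren are not
  modelled and contribute zero GPP).
* **Short-term meteorology acts multiplicatively or as a ceiling.**
  Variability not captured by NDVI and PAR is attributed to air
  temperature, soil water content (SWC), vapour pressure deficit (VPD)
  and (in principle) CO₂. A *scalar* response multiplies GPP and is
  clipped at one — a scalar can only decrease GPP. An *upper boundary* is
  a fitted ceiling that GPP cannot exceed. Temperature and VPD responses
  are logistic; the SWC response is Gaussian (bell-shaped), which lets it
  capture both drought stress at the dry end and waterlogging at the wet
  end. The CO₂ constraint is implemented but disabled by default: it
  degrades evaluation performance and the NDVI trend already carries any
  greening signal.
* **Parameters live on the upper envelope.** Daily flux data mix optimal
  and suppressed conditions. Calibration therefore extracts upper
  percentiles: per semi-month (day 1–15 / 16–end, the native NDVI
  compositing cadence), $F_\mathrm{opt}$ is the 95th percentile of daily
  GPP and $\alpha$ the median GPP/PAR ratio over low-light days (mean
  PAR < 25 W m⁻²). Semi-monthly $\alpha$ estimates above
  0.25 g C day⁻¹ W⁻¹ are unphysical and discarded; the median is taken
  over all low-light daily ratios first, so a single outlier day does not
  void a semi-month.

## The calibration chain

1. **Quality filtering** keeps days whose quality flag strictly exceeds
   0.5.
2. **Binned percentile regression.** Semi-monthly estimates are pooled
   per biome into 20 equal-width NDVI bins over the observed range
   (equal-width, not equal-count, so the bin centres are evenly spaced);
   a bin contributes only when it holds at least 5 estimates, and sparse
   bins are reported missing rather than zero. A bin-level percentile of
   the estimates is extracted and the logistic coupling is fit through
   the bin values by Levenberg–Marquardt least squares with moment-based
   starting values, a deterministic grid of perturbed restarts, and
   $a_{max}$ bounded in $(0, 3\max y]$. Constant or two-point input
   returns an explicit failure status instead of a degenerate curve.
3. **Variable importance.** A binary regression tree
   (variance-reduction splitting, depth 4, minimum leaf 20, no
   surrogates, no cross-validation so the fit is deterministic) of the
   daily *GPP scalar* — observed over NDVI/PAR-modelled GPP, undefined
   where the model predicts less than 0.1 g C m⁻² day⁻¹ — on the daily
   drivers ranks which driver still carries signal after the phenology.
4. **Constraint inclusion.** Walking the drivers in importance order,
   candidate scalar curves are fit to the binned 50th percentile of the
   GPP scalar (driver bin widths: T 5 °C, SWC 5 %Vol, VPD 25 hPa,
   CO₂ 5 ppm) and candidate boundaries to the binned 98th percentile of
   observed GPP. A candidate is retained only if it lowers the
   evaluation RMSE of constrained GPP; drivers whose effect NDVI already
   captures are thereby rejected. Fitted scalar curves are normalized so
   their maximum response is at most one.
5. **Percentile sensitivity.** The bin-level $F_\mathrm{opt}$ and
   $\alpha$ percentiles are selected by refitting the couplings for
   every pair on a percentile grid (default stride 5; a full 1–100 grid
   is configuration) and choosing the pair with the lowest daily
   evaluation RMSE, ties broken toward the lowest percentile
   (conservative GPP). The search runs **with the retained constraints
   applied**: the upper capacity percentiles are only optimal because
   the scalars explain the suppressed part of the data — without them
   the least-squares optimum drifts toward mean-matching and selects
   far lower percentiles. Whether evaluation RMSE should be computed at
   daily or semi-monthly aggregation was an open choice; daily is used.
   A 1-D search of the same kind is available per constraint scalar.
6. **Bootstrap parameterization.** 200 iterations resample calibration
   sites with replacement (site-years instead when a biome has a single
   site); every curve is refit on the included data and evaluated (RMSE,
   OLS slope, intercept, R², bias) on the omitted sites; an iteration
   that omits nothing is redrawn. Final parameters are means over
   iterations, uncertainties their standard deviations; everything is
   reproducible from one seed.
7. For deciduous biomes with few $\alpha$ estimates the fitted coupling
   can explode at high NDVI; an optional cap at the maximum binned
   $\alpha$ (`apply_alpha_limit`) mirrors how such biomes are handled.

## NDVI preprocessing

Semi-monthly NDVI composites are first despiked (a value deviating from
the running median of five by more than twice the series' standard
deviation becomes missing) and then smoothed per season with a
double-logistic curve — base level, amplitude, and a logistic green-up
and senescence transition — refit after down-weighting points that fall
below the curve (two envelope iterations, weights divided by the
adaptation strength 2). Cloud- and snow-contaminated composites bias
NDVI low, so biasing the fit toward the upper envelope recovers the
clean seasonal trajectory. This is a simplified seasonal smoother, not a
re-implementation of the full TIMESAT tool chain: the seasonal parameter
and Savitzky–Golay window arguments are accepted for configuration
compatibility but unused (the window belongs to a different smoothing
method), seasons are calendar years (one season per year), and a season
that fails to converge falls back to a flagged weighted running mean.
Smoothed composites expand to daily values piecewise-constantly.

## Upscaling and diagnostics

Calibrated models run over co-registered gridded NDVI and meteorology
(bilinear regridding for continuous fields, nearest-neighbour for
categorical maps, missing cells propagate). Budgets integrate
GPP × cell area over cells and days, with spherical-Earth cell areas
$R^2\,\Delta\lambda\,(\sin\varphi_2-\sin\varphi_1)$, $R = 6371$ km (the
area model is a package choice; a land-mask fraction within coastal
cells is not applied — cells are vegetated or not). Trends are ordinary
least squares of annual values on year with the usual slope standard
error; inter-annual variability is the sample standard deviation of the
detrended residuals; latitudinal profiles are area-weighted row means.
Land cover is static over a run. Propagating bootstrap parameter
uncertainty into budget ensembles is possible by drawing from the
reported parameter standard deviations but is not run by default.

Evaluation against reference series uses the classic three-way
decomposition — spatial (per-site means), inter-annual (per-year
across-site means), intra-annual (per-day-of-year across-site means) —
each summarized by OLS of model on reference (reference on the x-axis)
plus RMSE and bias of the raw pairs at that aggregation level; a fit is
only reported for more than two pairs. Annual GPP can also be compared
against annual NPP with the expectation NPP/GPP ≈ 0.5, reporting the
mean ratio and the fraction of points within a band around 2.

## The synthetic-data generator

Real calibrations need multi-decade satellite NDVI, reanalysis
meteorology and flux-network GPP, none of which can ship with a package.
The generator (`synthetic_truth()`, `gen_site()`, `gen_grid()`) draws
site records and gridded scenes from a fully known forward model, so
every stage of the chain is testable against ground truth. Its defaults
describe a seasonally green, warm, mostly sunny ecosystem:

* NDVI follows a double-logistic season (base 0.30, amplitude 0.45)
  with small composite noise and missing composites; the clean truth is
  kept alongside the degraded observation.
* Clear-sky shortwave is nearly flat over the year (260 ± 15 W m⁻², a
  tropical regime) and modulated by a semi-monthly cloud state — clear
  periods (transmittance 0.88–0.98, 20% of semi-months) against cloudy
  ones (0.30–0.75) — plus daily jitter. Deep-overcast days
  (transmittance 0.02–0.12, 5% of days, concentrated in the green
  season like monsoon cloud) provide the low-light days from which
  $\alpha$ is estimated.
* The true couplings keep a fixed saturation ratio
  $F_\mathrm{opt}/\alpha = 80$ W m⁻², so a clear day drives the light
  response to ~80–90% of saturation at every NDVI level.
* Daily quantum efficiency varies physiologically (median-one lognormal,
  σ = 0.30), and heavily overcast days carry a modest diffuse-light
  enhancement (12% at full overcast) — diffuse sky is known to raise
  canopy light-use efficiency — sized so that the median low-light
  GPP/PAR secant is an unbiased estimator of the true $\alpha$.
* Observed GPP is the true forward model times mean-one lognormal noise
  (σ = 0.10; multiplicative noise keeps GPP nonnegative), with 10% of
  days flagged low quality. Daily meteorology carries AR(1) persistence
  0.7, typical synoptic decorrelation.

These constants were fixed once, by analysis of the estimator geometry:
the saturation ratio and cloud mix place the semi-monthly
95th-percentile extraction so that the 95th bin percentile of capacity
estimates meets the true curve, and the diffuse term cancels the secant
concavity of the low-light ratio, so the generator's percentile truth is
(95, 50) by construction. `synthetic_truth_tair_stress()` is a preset
with a strong logistic air-temperature scalar and deliberately inert SWC
and VPD, used to exercise the constraint-inclusion logic.

What the generator deliberately does not emulate: sensor physics
(orbital drift, BRDF effects), flux-partitioning artefacts in tower GPP,
spatial autocorrelation between neighbouring sites, land-cover change,
and disturbance. Passing the recovery tests therefore shows that the
calibration chain inverts the model family it assumes under realistic
noise — not that the model family is adequate for any particular real
ecosystem.

## Numerical choices and problem sizes

* Percentiles use linear interpolation of the sorted sample (type 7)
  everywhere, matching the brute-force sorted-array definition.
* Nonlinear fits: Levenberg–Marquardt (maximum 200 iterations),
  moment-based initial values, deterministic perturbed restarts, best
  residual sum of squares wins; Gaussian fits whose width exceeds three
  times the data range or whose peak falls outside the data are flagged
  `"wide"` (monotone input cannot identify a peak).
* Ties in percentile selection break toward the lowest percentile.
* Division guards: the GPP scalar is missing (never infinite) when
  modelled GPP is below 0.1 g C m⁻² day⁻¹; empty bins are missing, not
  zero.
* Grid fields are stored north-up (descending latitude) and normalized
  on construction; text grids (long-format CSV with variable and units
  header lines) round-trip values bit-exactly via 17-digit decimal.
* Test and example problem sizes — 12 sites × 5 years for end-to-end
  recovery, 10 × 10 cells × a few years for scenes, stride-5 percentile
  grids — were chosen so the whole suite runs on a laptop in minutes
  while keeping every estimator in its asymptotic regime; the stride
  and sizes are configuration, not limits.

## Known limitations

* The logistic/Gaussian constraint curves are fit to binned percentiles,
  so constraint shape is only trustworthy where the driver range is well
  populated.
* The percentile sensitivity holds constraint curves fixed while the
  couplings vary; a fully joint refit per grid cell would be quadratic
  in cost and is not implemented.
* Single-site biomes bootstrap over site-years, which underestimates
  between-site variance by construction.
* The evaluation RMSE inside the sensitivity search is computed on the
  calibration data (in-sample); the bootstrap provides the out-of-sample
  statistics.
* NetCDF I/O is not provided; gridded exchange uses the documented CSV
  grid format.
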