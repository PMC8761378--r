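---
title: "Methods: from one-month passive samplers to lockdown-attributable mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from one-month passive samplers to lockdown-attributable mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

A one-month citizen-science campaign with NO~2~ diffusion tubes gives a dense
spatial snapshot of a city, but a snapshot taken just before a traffic
lockdown answers neither of the questions a health assessment needs: what was
the *annual* exposure of the resident population, and what would it have been
*without* the lockdown? `no2lockdown` implements the full chain that turns
the snapshot into both answers:

1. **Sampler QC** — eligibility filters (administrative boundary, outdoor
   placement, mounting height ≥ 3 m), a strong-outlier filter, and an
   accuracy calibration against co-located reference stations.
2. **Counterfactual forest** — a random forest of monthly station NO~2~ on
   meteorology, month and station id, trained on the four pre-lockdown years,
   predicts the lockdown months as they would have been under the observed
   2020 weather ("weather normalisation"). Out-of-bag (OOB) errors give
   prediction intervals.
3. **Annualization** — per-station ratios of the campaign-window mean to the
   annual mean give a city adjustment factor per scenario; dividing each
   sampler value by it yields annual estimates for the observed year
   (Scenario 1) and the no-lockdown counterfactual (Scenario 2).
4. **Spatial model (LURF)** — a land-use random forest maps multi-radius
   circular-buffer predictors (road lengths, traffic loads, land cover,
   population, traffic lights, distances, elevation, imperviousness, night
   lights) to the annual estimates and predicts every grid-cell centroid.
5. **Health impact assessment** — census blocks inherit the mean of
   intersecting cells, deaths are redistributed by population where mortality
   is only available at a coarser unit, and attributable deaths are
   `AF × D` with

   AF = 1 − RR^(−c/10),  c = max(0, exposure − threshold),

   RR = 1.04 per 10 µg/m³ (95% CI 1.02–1.07) for all-cause mortality and a
   counterfactual threshold of 10 µg/m³ (the WHO 2021 annual guideline).
   The lockdown effect is the difference of the two scenario totals.

Because the original campaign and network data are not redistributable, the
package ships a synthetic-city generator whose ground truth (the injected
lockdown multiplier, the true annual fields, the true attributable totals)
makes every stage testable end to end.

## The synthetic city

`city_config()` fixes the study conditions; `generate_city()` is fully
deterministic given its seed.

* **Spatial field.** Roads (highway/major/secondary/local, with light- and
  heavy-vehicle densities) are rasterized to the grid; the no-lockdown annual
  field is `background + β·log(1 + traffic_load)` smoothed with a disc
  kernel (default radius 250 m), emulating dispersion and reproducing the
  empirical dominance of traffic-load buffer variables in the spatial model.
* **Seasonality.** Month `m` carries the multiplier `1 + A·cos(2π(m−1)/12)`
  (winter-high, mean exactly 1). The default amplitude 0.45 puts the
  campaign-window/annual ratio near 1.35, in the range observed for
  winter-polluted European cities.
* **Meteorology.** Monthly climatologies (sinusoids) plus AR(1) anomalies
  for dew point, temperature, sea-level pressure, cumulative rain and wind
  speed; wind direction is uniform circular. Only the *anomalies* perturb
  NO~2~ (multiplicatively, small coefficients), so each calendar month's
  expected concentration stays on its climatology and the analytic
  window/annual ratio `campaign_window_factor()` stays closed-form.
* **Lockdown.** March–May 2020 concentrations are multiplied by
  λ ∈ (0, 1]; the default 0.6 matches the ~40% urban NO~2~ reductions
  reported for strict 2020 lockdowns. The campaign window (Feb 8–Mar 7)
  overlaps March, so λ applies to the whole of March in both the station
  series and the sampler field; this whole-month convention keeps samplers,
  stations and the analytic window factor mutually consistent.
* **Daily series.** Daily 2020 values are the monthly value times a smooth
  within-month sinusoidal modulation (mean exactly 1 over each month) times
  lognormal noise, so campaign-window means differ from calendar-month means
  as in real data.
* **Samplers.** Values are the campaign-window field at the containing cell
  times the true accuracy factor (default 0.92 — diffusion tubes under-read)
  times lognormal noise (sd 0.08, typical of co-location studies). Small
  fractions are made ineligible (2% indoor, 2% below 3 m, 2% outside the
  border) to exercise the QC stage.
* **Blocks and deaths.** Rectangular census blocks tile the grid; population
  decays from the centre with lognormal heterogeneity and sums exactly to
  the configured total; deaths are Poisson with mean `population ×
  death_rate` (default 0.011/yr, the Italian crude rate). Blocks nest in
  districts.

What the generator does **not** emulate: street-canyon chemistry, station
siting bias (urban background vs traffic), day-of-week traffic cycles,
spatially varying meteorology, and real street-network geometry. Passing
tests therefore demonstrate the correctness and internal consistency of the
pipeline, not the accuracy of any real-city estimate.

## Numerical conventions

* **Percentiles** everywhere (outlier rule, OOB quantiles, field summaries)
  use linear interpolation of order statistics (`quantile(type = 7)`); the
  outlier bounds `P25 − 3·IQR`, `P75 + 3·IQR` are computed once on the full
  eligible pool, with no re-iteration after removal.
* **Eligibility order** is boundary → indoor → height → outlier, each
  sampler counted once under the first filter that removes it, so outlier
  percentiles see eligible samples only.
* **Boundary containment** is closed: points on an edge or vertex are kept.
* **Accuracy correction** divides by the factor (the factor is a
  passive/reference ratio, so division maps samplers onto the reference
  scale); a `direction = "multiply"` switch covers the opposite convention.
* **Annual means** are unweighted means of twelve monthly means (the
  replacement of March–May works in whole months); day-weighting is
  available behind a flag.
* **Wind direction** enters the forest as (sin θ, cos θ) so 0° and 360°
  coincide.
* **Forest defaults**: 500 trees, `mtry = ⌈p/3⌉`, minimum node size 5, fixed
  seeds — standard regression-forest defaults, exposed in the configuration.
* **OOB intervals** use one pooled empirical error distribution, so the
  interval width is identical at every prediction point; empirical quantiles
  need not bracket the point prediction, but `lower ≤ upper` always holds.
* **Block linkage** uses non-strict rectangle intersection (shared edges and
  corners count) and the unweighted mean of intersecting cells;
  area-weighting is available behind a flag.
* **Deaths** may be fractional after population-weighted redistribution;
  totals are rounded only for display.

## Uncertainty propagation

The point run uses the mean adjustment factors, the forest point predictions
and the point grid field. Variation ranges are produced as alternative
complete runs, one labelled source at a time:

* minimum/maximum station ratios as the annual adjustment factor (both
  scenarios);
* the OOB interval bounds of the counterfactual March–May predictions
  (Scenario 2 only), propagated through the factor and the spatial model;
* the OOB bounds of the predicted grid field (both scenarios);
* the RR confidence bounds (1.02, 1.07), reported separately as the
  epidemiological CI.

`uncertainty_ledger()` returns one (lo, hi) attributable-death pair per
source; sources are never combined in quadrature.

## Design decisions taken where the method was open

* The package is organised tidyverse-style: tibbles in and out, `tidy()` and
  `glance()` methods on forest fits, `autoplot()` for fields and fits. The
  pipeline stages remain independently callable functions; `run_stage()`
  adds a file-based runner whose CSV artifacts carry a config hash and seed.
* All planar geometry (point-in-polygon, segment–circle chords,
  point-segment distances, rectangle intersection) is closed-form Euclidean
  math implemented in the package; coordinates are metres in a projected
  CRS and buffers are Euclidean circles.
* Buffer land-cover percentages and buffer population aggregate raster cell
  centroids within the radius (nearest-cell fallback below the raster
  resolution); road lengths and traffic loads use exact chord clipping.
  All (variable, radius) combinations are generated and variable selection
  is left to the forest.
* The smoothing-kernel radius of the generator (250 m) is a free parameter:
  the residual spatial autocorrelation of urban NO~2~ at sub-km scales is
  not well constrained, and the value was fixed once at a plausible
  dispersion scale.
* Outlier bounds are computed per city (one pool per campaign), and the
  single shipped accuracy factor applies to all samplers of a campaign.

## Problem sizes used by the test suite

The unit suite exercises a 15 × 15-cell city (12 stations, 120 samplers,
25 blocks) with 150–300-tree forests; the end-to-end recovery check and the
worked examples in the README use the default 30 × 30-cell city (20
stations, 300 samplers, 64 blocks) with 500-tree forests. These sizes keep
every property of interest measurable (field recovery correlation, interval
coverage on 500 test points, replicate-averaged null bias) while the whole
suite runs in well under a minute.

## Known limitations

* Adjustment factors are city-wide: site-type-specific factors (urban
  background vs traffic) are not modelled, which compresses the spatial
  contrast of the annual estimates — the same simplification the
  fixed-factor annualization approach is known for.
* The counterfactual forest attenuates city-wide meteorology anomalies it
  has seen only ~48 distinct realisations of; single-realisation biases of
  ±2–3 µg/m³ in a three-month mean are expected and average out over
  replicates.
* The attributable-fraction model is all-cause mortality only; morbidity,
  life-years and age-stratified risks are out of scope.
* Predictions of a regression forest cannot leave the training response
  range, so extreme unsampled locations are flattened toward the observed
  range.
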