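# no2lockdown

Estimating what a traffic lockdown did to annual NO₂ exposure and
NO₂-attributable mortality, at neighbourhood scale, from a one-month
citizen-science campaign.

A dense snapshot of diffusion-tube measurements taken just before a lockdown
answers neither of the questions a health assessment needs: what was the
**annual** exposure of the resident population, and what would it have been
**without** the lockdown? This package implements the full multi-step chain
that answers both, plus a synthetic-city generator with known ground truth so
the chain can be validated end to end. It is aimed at air-quality
epidemiologists and environmental-health analysts working with passive
sampler campaigns and regulatory monitoring networks.

## The method

1. **Sampler QC** — exclude samplers outside the administrative border,
   indoors, or mounted below 3 m; flag strong outliers with
   `x < P25 − 3·IQR` or `x > P75 + 3·IQR` (percentiles computed once on the
   full pool); correct by the co-location accuracy factor (mean
   passive/station ratio, default 0.92).
2. **Counterfactual forest** — a random forest of monthly station NO₂ on
   dew point, temperature, sea-level pressure, cumulative rain, wind
   (speed, direction), month and station id, trained on 2016–2019, predicts
   March–May 2020 under the observed 2020 weather — the no-lockdown
   counterfactual. Out-of-bag errors `Dᵢ = Yᵢ − Ŷᵢ` give prediction
   intervals `[Ŷ + D₍α/2₎, Ŷ + D₍1−α/2₎]` (α = 0.05).
3. **Annualization** — per station, the ratio of the campaign-window mean
   (Feb 8 – Mar 7) to the annual mean; the city factor is the mean ratio.
   Scenario 1 (lockdown) uses the observed 2020 annual mean; Scenario 2 (no
   lockdown) recomputes it with March–May replaced by the forest
   predictions. Each sampler's 1-month value divided by the factor is its
   annual estimate.
4. **Land Use Random Forest** — circular-buffer predictors at 20–1000 m
   (road length and traffic load `length × vehicle density` by road type,
   land-cover percentages, population, traffic lights, distances, elevation,
   imperviousness, night lights) map the annual estimates to every grid-cell
   centroid, with OOB bounds.
5. **Health impact assessment** — census blocks take the mean of
   intersecting cells; attributable deaths are `AF × D` per block with

   `AF = 1 − RR^(−c/10)`, `c = max(0, exposure − 10 µg/m³)`,

   RR = 1.04 per 10 µg/m³ (95% CI 1.02–1.07). The lockdown effect is the
   difference between the two scenario totals, with uncertainty propagated
   as alternative complete runs (min/max factors, counterfactual interval
   bounds, grid interval bounds, RR CI).

## Worked example

```r
library(no2lockdown)

cfg <- pipeline_config(city = city_config(seed = 2024))
res <- run_pipeline(cfg)
res
#> <pipeline_result>
#>   factors: S1 1.312, S2 1.184
#>   field means: S1 31.7, S2 35.1 ug/m3
#>   attributable deaths: S1 47, S2 54; prevented 7 (+14.8%)
```

The synthetic city (30 × 30 cells of 100 m, 20 stations, 300 samplers,
50,000 inhabitants) was generated with a lockdown multiplier λ = 0.6 on
March–May 2020. The campaign-window/annual factor is larger for Scenario 1
(1.312) than for Scenario 2 (1.184) because the counterfactual annual mean
is higher — exactly the pattern that makes the no-lockdown annual estimates
exceed the observed-scenario ones:

```r
res$factors$S1
#> <scenario_factors> Synthia S1: mean 1.312 (sd 0.044), min 1.216, max 1.433 over 20 stations
res$factors$S2
#> <scenario_factors> Synthia S2: mean 1.184 (sd 0.043), min 1.109, max 1.297 over 20 stations

glance(res$counterfactual$fit)   # weather-normalisation fit statistics
#>   oob_r2  rmse pred_r2 rmspe intercept slope     n
#> 1  0.972  2.35   0.974  2.35     -1.54  1.05   960
```

City-mean annual NO₂ rises from 31.7 to 35.1 µg/m³ (+10.8%) without the
lockdown, and the attributable-death total from 47 to 54 (+14.8%): the
lockdown prevented about 7 deaths in this 50,000-person city, against a
generator ground truth of 6.2. Per-source uncertainty for Scenario 2:

```r
res$uncertainty$S2
#>   source                lo    hi
#> 1 point               54.3  54.3
#> 2 rr_ci               28.2  90.3
#> 3 adjustment_factors  48.0  59.1
#> 4 rf_interval         51.3  57.6
#> 5 lurf_oob            28.6  73.3
```

`autoplot(res$fields$S1, res$city$grid)` maps the predicted field;
`tidy(res$lurf$S1)` ranks predictor importance (traffic-load buffers
dominate, as they should for a traffic-driven field). A file-based runner is
also available: `run_stage("generate", cfg, "out/")`, then `"qc"`,
`"counterfactual"`, `"annualize"`, `"lurf"`, `"hia"`, `"report"`.

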