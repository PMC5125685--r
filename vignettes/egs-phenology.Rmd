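---
title: "Modelling the end of the growing season with a temperature-adaptive threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the end of the growing season with a temperature-adaptive threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egsmodel)
```

## The model

The end of the growing season (EGS) — the day leaf senescence begins — is a
first-order control on canopy duration and autumn carbon uptake, and one of
the weakest links in dynamic global vegetation models. The classical
phenology rules in the IBIS vegetation model trigger leaf fall for trees
when the 10-day running-mean air temperature falls below 0&nbsp;°C or to
within 5&nbsp;°C of the coldest monthly temperature, and for grasses and
shrubs when it reaches 0&nbsp;°C. Fixed thresholds of this kind
systematically misplace senescence across climatic gradients, because
plants adapt their temperature requirements to their local environment: a
birch in the boreal zone sheds leaves at a lower temperature than an oak in
a warm temperate plain.

`egsmodel` implements a temperature-dominated EGS model in which the
critical threshold itself adapts to the local climate. For a pixel with
mean annual temperature $T_{avg}$, senescence begins on the first day $d$
after midsummer (day-of-year $\ge$ 183) for which the trailing 10-day
running-mean temperature satisfies

$$\bar T_{10}(d) < T_{crit} = a + b \, T_{avg},$$

with biome-specific parameters $a$ (°C) and $b$ (dimensionless, °C per °C
of mean annual temperature). Calibrated against satellite-observed
senescence dates over the Northern Hemisphere, thresholds land in a
7–9&nbsp;°C band, increasing toward warmer climates; grassland thresholds
sit below those of woody vegetation at the same latitude. The calibrated
reference set shipped as `default_biome_params()` ranges from
$(a, b) = (8, 0.272)$ for evergreen needle-leaf forest to $(7, 0.02)$ for
grassland.

Conventions that matter to reproducibility:

* **Window alignment.** The 10-day running mean is a *trailing* window
  ending on the evaluated day — senescence responds to the temperatures
  that precede a day — with a truncated mean over days $1..d$ for the
  first nine days of the year (irrelevant to the July-onward search).
* **Midsummer gate.** The search starts at a fixed day-of-year 183 in all
  years (July 2 in non-leap years). The one-day leap shift is below the
  model's resolution.
* **Strictness.** The adaptive trigger is strict (`<`, "fell below"); the
  IBIS grass/shrub trigger is inclusive (`<=` 0&nbsp;°C, "reaches"). The
  IBIS tree rule is applied as the disjunction of its two triggers,
  equivalent to a single threshold $\max(0,\, T_{cold} + 5)$&nbsp;°C, and
  both baselines get the same midsummer gate as the adaptive model so the
  comparison is like-for-like.
* **$T_{avg}$.** Climatological — all daily values pooled over the years
  of record — because the threshold parameters are static over a study
  period. A per-year variant is available via
  `prepare_pixel_years(tavg_mode = "per_year")`.
* **Sentinel.** A year whose running mean never crosses the threshold
  returns `NA` ("no senescence detected"), never a fabricated date.
  Metrics exclude sentinel pairs and report their count.
* **IBIS biome mapping.** The grass/shrub rule is applied to grassland,
  closed and open shrubland and savanna; all forests, woody savanna and
  permanent wetland use the tree rule.
* Temperatures are in °C throughout; day-of-year is 1-based.

## Calibration

Parameters are estimated per biome by minimising the error sum of squares
(ESS, days²) between predicted and observed EGS dates over
calibration pixel-years,

$$\mathrm{ESS}(a, b) = \sum_i \left(\hat d_i(a,b) - d_i\right)^2 ,$$

with pixels randomly split half/half into calibration and validation sets
(`split_pixels()`; the seed is a required, recorded input, and the split is
drawn per biome). All years of a calibration pixel enter as separate
pixel-years. A pixel-year whose prediction is the sentinel contributes a
censored penalty $(365 - d_i)^2$, which keeps the objective finite and
pushes the search back toward parameter regions that produce a crossing;
dropping such pixel-years instead is available via `sentinel = "drop"`.

Because predictions are integer days, the ESS surface is *piecewise
constant* in $(a, b)$: derivative-based least-squares algorithms have a
zero gradient almost everywhere and are ill-posed here. `fit_biome()`
therefore uses a three-level coarse-to-fine grid search — resolutions 1,
0.2, 0.05&nbsp;°C in $a$ and 0.05, 0.01, 0.002 in $b$, each level centred
on the previous optimum — which is exhaustive over the search box
($a \in [-20, 20]$&nbsp;°C, $b \in [-1, 1]$) at the coarse level and exact
to the finest resolution, matching the three decimals to which $b$ is
conventionally reported. Each refinement grid contains the previous best
point, so the best ESS is non-increasing across levels.

Two consequences of the flat-plateau geometry are worth knowing:

* **Ties.** At the finest level the minimising set is typically a small
  plateau (with noise-free observations, a region of exactly zero ESS).
  `fit_biome()` returns the centroid of that set, a symmetric tie-break
  that lands mid-plateau, and keeps the single best grid point if the
  centroid happens to score worse (the plateau need not be convex).
* **Held-out quantisation.** Parameters anywhere on the calibration
  plateau reproduce the *calibration* pixel-years exactly, but may move a
  few *validation* predictions by one day, because each pixel-year accepts
  an interval of thresholds roughly one day's cooling (~0.2–0.4&nbsp;°C)
  wide. Zero-noise validation RMSE is therefore bounded by about a day
  rather than identically zero.

`predict_egs_novel(fractional = TRUE)` interpolates the crossing linearly
between the bracketing days, giving a prediction continuous in the
threshold from which a smooth objective could be built for gradient-based
optimisers; the shipped calibrator keeps the integer-day objective, which
already recovers parameters exactly at the reported precision.

`fit_biome()` requires at least 10 pixel-years and warns when the
calibration set spans less than 1&nbsp;°C of $T_{avg}$, where $a$ and $b$
are not jointly identifiable (any $(a + b\,\bar T)$-preserving trade-off
fits equally well).

## Evaluation

`evaluate_predictions()` reports, per biome and pooled:

* **R²**, by two conventions: the squared Pearson correlation between
  observed and predicted dates (the headline number and the dominant
  convention in phenology validation) and the sum-of-squares form
  $1 - SSE/SST$, which additionally penalises bias and can be negative.
  Both are computed; pick deliberately.
* **RMSE** and the **mean absolute error** in days (RMSE ≥ MAE always).
* The **cumulative within-$k$-day curve** at integer $k$, from which
  "fraction of pixels within 10 (15) days" is read off bit-reproducibly.
* Sentinel counts, reported rather than imputed.

`observed_threshold()` evaluates the running mean at an *observed*
senescence date, the per-pixel empirical threshold; regressing it on
$T_{avg}$ across pixels (`threshold_regression()`) recovers $(a, b)$
directly on model-generated data and is the package's analogue of the
threshold-versus-climate scatter that motivates the model. On a fixture
generated without any noise the regression slope is recovered to ±0.01;
the residual scatter that remains is the one-day quantisation of the
crossing (the measured threshold undershoots $T_{crit}$ by up to one
day's cooling step), so $r \to 1$ only for biomes whose slope signal is
large relative to ~0.1&nbsp;°C.

`interannual_series()` and `trend_slope()` aggregate pixel-years to annual
area means per biome and fit an OLS trend in days/yr with a two-sided
t-test of zero slope (reported only with ≥ 3 years; an exactly linear
series reports $p = 0$ rather than relying on a degenerate t-statistic).

## The synthetic generator

Real inputs at hemispheric scale are satellite phenology (observed EGS per
pixel-year), a land-cover classification, and reanalysis daily
temperature. For development and validation the package generates a
self-consistent replacement with known ground truth
(`generate_dataset()`):

* **Daily temperature**: a sinusoidal annual cycle
  $T(d) = T_{avg} + A \cos\!\big(2\pi (d - 200)/365\big)$ plus AR(1) noise
  with coefficient 0.7 and innovation sd 2&nbsp;°C (stationary sd
  ≈ 2.8&nbsp;°C), continuous across year boundaries — synoptic-scale
  persistence typical of mid-latitude weather. The warmest day defaults to
  day-of-year 200 (mid-July).
* **Pixels**: per biome, $T_{avg}$ is uniform over a configurable
  climatological range (defaults span e.g. −15…5&nbsp;°C for deciduous
  needle-leaf forest, 15…25&nbsp;°C for savanna). The seasonal amplitude
  is $A = \max(U(12, 18),\ |T_{avg} - 8| + 4)$&nbsp;°C: the uniform part
  is a typical mid-latitude seasonal range, and the floor — larger for
  climates far from the ~8&nbsp;°C threshold band — is a continentality
  proxy guaranteeing that every pixel's annual cycle passes through its
  threshold *after* midsummer (summer peak above, late-year trough below)
  while the autumn cooling rate $2\pi A/365$ stays within
  0.05–0.5&nbsp;°C/day. A pixel that still fails to cross (deep noise
  tail) is redrawn, up to 20 times.
* **Observed EGS**: the adaptive model's prediction at the pixel's pooled
  climatology and the configured ground-truth $(a, b)$ (default: the
  reference parameter set), plus rounded Gaussian observation noise
  (default sd 5 days, a typical satellite retrieval uncertainty), clipped
  to [183, 365]. With zero noise the fixture is exactly model-generated,
  so the full pipeline must be exact on it: prediction error 0, R² = 1,
  and recalibration must return to the generating parameters within the
  finest grid resolution.
* **Imposed trend**: an optional warming-driven shift of $s$ days/yr adds
  per-pixel linear warming at rate
  $s \cdot (2\pi A / 365)\,|\sin\theta^\*|$ °C/yr, where
  $\cos\theta^\* = (T_{crit} - T_{avg})/A$ locates the expected crossing
  on the annual cycle — i.e. the warming is scaled to the local autumn
  cooling rate so the first-order EGS shift is $s$ for every pixel — and
  is centred on the middle year so the pooled $T_{avg}$ (hence the
  threshold) is unchanged.

Everything is deterministic given the config's seed, and generation
restores the caller's RNG state.

What the generator does **not** emulate: vegetation-index retrieval and
its snow/cloud failure modes, spatial autocorrelation between pixels,
moisture effects (the drought-deciduous pathway is out of scope), land
cover misclassification, and reanalysis error structure. Passing the
recovery experiments therefore demonstrates that the calibration and
evaluation machinery is correct and well-conditioned under the model's own
assumptions — not that the model is an unbiased description of any
particular satellite product.

## Problem sizes and tolerances

The recovery experiments use 500 pixels × 3 years per biome (1500
pixel-years), a size at which the zero-noise ESS minimum pins $a$ to well
within ±0.5&nbsp;°C and $b$ to within ±0.02 of truth, and with 5-day
observation noise to within ±1&nbsp;°C and ±0.05. Trend recovery uses 200
pixels × 10 years and recovers an imposed 0.5 day/yr shift to ±0.2. The
oracle-equivalence suite checks all three prediction rules against a
literal day-by-day scan on 1000 random series. These sizes are the
package's test conditions; larger grids simply scale linearly in pixels.

## Limitations

* Start-of-season phenology, the drought-deciduous (photosynthesis-based)
  trigger, and sub-daily temperature are out of scope.
* Parameters carry no uncertainty estimates (no standard errors or
  bootstrap intervals); the grid search returns a point estimate with its
  objective value.
* Temperature input is a long-format CSV (or an in-memory store); pixels
  are treated as points in WGS84, with no grid geometry or reprojection.
* The evaluation treats pixel-years as independent; spatial and temporal
  autocorrelation are not corrected for.
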