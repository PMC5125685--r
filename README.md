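# egsmodel

Predicting the **end of the growing season** (EGS) — the onset of autumn
leaf senescence — from daily mean air temperature, for temperate and
boreal vegetation at continental scale.

Classical phenology rules in dynamic vegetation models (e.g. IBIS) drop
leaves when the 10-day running-mean temperature falls below a *fixed*
threshold (0 °C, or 5 °C above the coldest monthly temperature). Plants,
however, adapt their temperature requirements to the climate they grow in,
and fixed thresholds misplace senescence by weeks across climatic
gradients. `egsmodel` implements an adaptive-threshold model: after
midsummer (day-of-year ≥ 183), senescence begins on the first day *d* with

    T̄₁₀(d) < T_crit,      T_crit = a + b · T_avg

where T̄₁₀ is the trailing 10-day running-mean temperature, T_avg the
pixel's mean annual temperature, and (a, b) biome-specific parameters
calibrated against satellite-observed senescence dates (reference set in
`default_biome_params()`, e.g. a = 8 °C, b = 0.272 for evergreen
needle-leaf forest). The package is aimed at land-surface/phenology
modellers who want to calibrate, validate, or embed the rule.

It provides:

* the adaptive model and the original IBIS tree and grass/shrub rules
  (`predict_egs_novel()`, `predict_egs_ibis_tree()`,
  `predict_egs_ibis_grass()`, vectorised via `predict_egs()`);
* biome-wise calibration by coarse-to-fine grid search on the error sum of
  squares, with a random calibration/validation pixel split
  (`split_pixels()`, `fit_biome()`, `calibrate_all()`);
* a validation suite: R², RMSE, mean absolute error, cumulative
  within-k-day agreement, empirical per-pixel thresholds and their
  regression on climate, interannual trends (`evaluate_predictions()`,
  `observed_threshold()`, `threshold_regression()`, `trend_slope()`);
* a synthetic gridded-data generator with known ground truth
  (`generate_dataset()`) for parameter-recovery experiments;
* plain-text CSV/JSON I/O and a command-line interface
  (`egs_cli()`, installed script `inst/cli/egs.R`).

## Worked example

Simulate two biomes with 5-day observation noise, calibrate on half the
pixels, and compare the adaptive model with the IBIS baseline:

```r
library(egsmodel)

cfg <- synthetic_config(
  n_pixels_per_biome = 60,
  biomes = default_biome_ranges()[c(1, 9), ],  # evergreen needle-leaf, grassland
  egs_noise_sd = 5, years = 2001:2003, seed = 2024)
ds <- generate_dataset(cfg)
#> synthetic dataset: 360 pixel-years, 120 pixels, 2 biome(s), years 2001-2003 (seed 2024)

fits <- calibrate_all(ds$pixels, ds$temperature, split_seed = 11)
params_table(fits)[, 1:5]
#>                         biome    a     b  ess n_pixel_years
#> 1 evergreen_needleleaf_forest 8.00 0.270 2402            90
#> 2                   grassland 6.95 0.022 2977            90

py   <- prepare_pixel_years(ds$pixels, ds$temperature)
pred <- predict_egs(py, "novel", params = params_table(fits))
evaluate_predictions(ds$pixels$biome, ds$pixels$egs_doy_observed, pred)$metrics
#>                       biome   n r_squared  rmse  mae within_10 within_15
#>                         all 360     0.966  5.31 4.11     0.958     0.992
#> evergreen_needleleaf_forest 180     0.953  5.06 3.91     0.961     0.994
#>                   grassland 180     0.966  5.54 4.32     0.956     0.989
```

Despite the noise, calibration returns to the generating parameters
(truth: a = 8, b = 0.272 for the forest; 7, 0.02 for grassland), and the
adaptive model reproduces 96 % of pixel-years within 10 days (RMSE
≈ 5 days — the injected observation noise itself). The same pixels scored
with the fixed-threshold baseline (`predict_egs(py, "ibis")`) give RMSE
≈ 35 days and only 2 % within 10 days: the gap the adaptive threshold
closes.

The command line wraps the same pipeline:

```sh
Rscript inst/cli/egs.R simulate  --out fx --seed 42 --n-pixels 50
Rscript inst/cli/egs.R calibrate --input fx/pixels.csv --temperature fx/temperature.csv \
                                 --split-seed 7 --out fit
Rscript inst/cli/egs.R evaluate  --input fx/pixels.csv --temperature fx/temperature.csv \
                                 --params fit/params.csv --model novel --out report
```

Every run writes its resolved configuration and seeds to
`run_config.json` next to its outputs.

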