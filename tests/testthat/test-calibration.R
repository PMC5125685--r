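test_that("pixel split is disjoint, exhaustive and deterministic", {
  ids <- sprintf("px%03d", 1:100)
  sp <- split_pixels(ids, 0.5, seed = 7)
  expect_length(sp$calibration_pixels, 50)
  expect_length(sp$validation_pixels, 50)
  expect_length(intersect(sp$calibration_pixels, sp$validation_pixels), 0)
  expect_setequal(c(sp$calibration_pixels, sp$validation_pixels), ids)

  sp2 <- split_pixels(ids, 0.5, seed = 7)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_pixels(ids, 0.5, seed = 8)))

  # odd counts round half up
  sp7 <- split_pixels(letters[1:7], 0.5, seed = 1)
  expect_length(sp7$calibration_pixels, 4)
  expect_length(sp7$validation_pixels, 3)

  expect_error(split_pixels("a", 0.5, seed = 1), "at least 2")
  expect_error(split_pixels(letters[1:4], 1.2, seed = 1), "fraction")
})

test_that("ESS accumulates squared day errors with a censored penalty", {
  expect_equal(ess_from_predictions(c(280L, 290L), c(282L, 287L)), 13)
  expect_equal(ess_from_predictions(c(280L, 290L), c(280L, 290L)), 0)
  expect_equal(ess_from_predictions(c(280L, NA), c(282L, 300L)),
               4 + (365 - 300)^2)
  expect_equal(ess_from_predictions(c(280L, NA), c(282L, 300L),
                                    sentinel = "drop"), 4)
  expect_error(ess_from_predictions(integer(0), integer(0)), "non-empty")
})

test_that("vectorised predictions agree with the per-series scalar path", {
  ds <- small_fixture(biomes_idx = c(1L, 9L), n_pixels = 15L)
  py <- prepare_pixel_years(ds$pixels, ds$temperature)
  params <- default_biome_params()
  vec <- predict_egs(py, "novel", params = params)
  store <- temperature_store(ds$temperature)
  for (i in seq_along(vec)) {
    series <- store[[py$pixel_id[[i]]]][[as.character(py$year[[i]])]]
    cl <- pixel_climate(store[[py$pixel_id[[i]]]])
    pr <- params[params$biome == py$biome[[i]], ]
    expect_identical(vec[[i]],
                     predict_egs_novel(series, tcrit(pr$a, pr$b, cl$t_avg)))
  }
  # objective consistency with the standalone accumulator
  same_params <- data.frame(biome = unique(py$biome), a = 8, b = 0.272)
  expect_equal(ess_objective(8, 0.272, py),
               ess_from_predictions(
                 predict_egs(py, "novel", params = same_params),
                 py$observed))
})

test_that("IBIS predictions agree with the per-series scalar rules", {
  ds <- small_fixture(biomes_idx = c(2L, 9L), n_pixels = 10L)
  py <- prepare_pixel_years(ds$pixels, ds$temperature)
  vec <- predict_egs(py, "ibis")
  store <- temperature_store(ds$temperature)
  for (i in seq_along(vec)) {
    series <- store[[py$pixel_id[[i]]]][[as.character(py$year[[i]])]]
    cl <- pixel_climate(store[[py$pixel_id[[i]]]])
    ref <- if (py$biome[[i]] %in% ibis_grass_biomes()) {
      predict_egs_ibis_grass(series)
    } else {
      predict_egs_ibis_tree(series, cl$t_coldest_month)
    }
    expect_identical(vec[[i]], ref)
  }
})

test_that("grid search recovers zero-noise ground truth", {
  ds <- small_fixture(biomes_idx = 1L, n_pixels = 60L)  # ENF: a=8, b=0.272
  py <- prepare_pixel_years(ds$pixels, ds$temperature)
  fit <- fit_biome(py)
  expect_equal(fit$a, 8, tolerance = 0.5 / 8)
  expect_lt(abs(fit$b - 0.272), 0.02)
  expect_equal(fit$ess, 0)
  expect_equal(fit$n_sentinel, 0)
  # the fitted optimum is at least as good as the truth and as random probes
  expect_lte(fit$ess, ess_objective(8, 0.272, py))
  set.seed(5)
  probes <- vapply(1:300, function(i) {
    ess_objective(runif(1, -20, 20), runif(1, -1, 1), py)
  }, numeric(1))
  expect_true(all(fit$ess <= probes))
  # refinement never worsens the best objective
  expect_true(all(diff(fit$search_trace$ess) <= 0))
})

test_that("a flat threshold (b = 0) is recovered as flat", {
  truth <- default_biome_params()
  truth$b[truth$biome == "grassland"] <- 0
  cfg <- synthetic_config(
    n_pixels_per_biome = 40L,
    biomes = default_biome_ranges()[9, , drop = FALSE],  # grassland
    params = truth, egs_noise_sd = 0, years = 2001:2002, seed = 12)
  ds <- generate_dataset(cfg)
  py <- prepare_pixel_years(ds$pixels, ds$temperature)
  fit <- fit_biome(py)
  expect_lt(abs(fit$b), 0.01)
  expect_equal(fit$ess, 0)
})

test_that("calibration guards identifiability", {
  ds <- small_fixture(n_pixels = 3L, years = 2001)
  py <- prepare_pixel_years(ds$pixels, ds$temperature)
  expect_error(fit_biome(py), "at least 10")

  # degenerate t_avg spread: warn but still return a result
  rng <- default_biome_ranges()[1, , drop = FALSE]
  rng$t_avg_min <- 4.9
  rng$t_avg_max <- 5.1
  ds2 <- generate_dataset(synthetic_config(
    n_pixels_per_biome = 12L, biomes = rng, egs_noise_sd = 0,
    years = 2001, seed = 3))
  py2 <- prepare_pixel_years(ds2$pixels, ds2$temperature)
  expect_warning(fit2 <- fit_biome(py2), "identifiable")
  expect_true(length(fit2$warnings) > 0)
})

test_that("calibrate_all fits each biome on its calibration half only", {
  ds <- small_fixture(biomes_idx = c(1L, 3L, 9L), n_pixels = 24L,
                      seed = 31L)
  res <- calibrate_all(ds$pixels, ds$temperature, split_seed = 99)
  expect_length(res, 3)
  expect_setequal(names(res), unique(ds$pixels$biome))
  splits <- attr(res, "splits")
  for (bio in names(res)) {
    sp <- splits[[bio]]
    n_cal_years <- sum(ds$pixels$biome == bio &
                         ds$pixels$pixel_id %in% sp$calibration_pixels)
    expect_equal(res[[bio]]$n_pixel_years, n_cal_years)
    expect_length(intersect(sp$calibration_pixels, sp$validation_pixels), 0)
    # zero-noise truth is recovered per biome
    truth <- default_biome_params()
    truth <- truth[truth$biome == bio, ]
    expect_lt(abs(res[[bio]]$a - truth$a), 0.5)
    expect_lt(abs(res[[bio]]$b - truth$b), 0.02)
  }
  tab <- params_table(res)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("biome", "a", "b", "ess", "split_seed") %in% names(tab)))
})

test_that("biomes with too little data are skipped with a warning", {
  ds <- small_fixture(biomes_idx = c(1L, 9L), n_pixels = 24L, seed = 8L)
  # cripple grassland to a single pixel
  keep <- ds$pixels$biome != "grassland" |
    ds$pixels$pixel_id == ds$pixels$pixel_id[ds$pixels$biome == "grassland"][1]
  pixels <- ds$pixels[keep, ]
  expect_warning(
    res <- calibrate_all(pixels, ds$temperature, split_seed = 1),
    "skipped|fewer")
  expect_false("grassland" %in% names(res))
  expect_true("evergreen_needleleaf_forest" %in% names(res))
})
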