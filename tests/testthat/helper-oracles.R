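# Independent brute-force oracles: literal day-by-day loops, kept free of
# any package internals so they can arbitrate the vectorised code paths.

naive_running_mean <- function(values, window) {
  n <- length(values)
  out <- numeric(n)
  for (d in seq_len(n)) {
    lo <- max(1L, d - window + 1L)
    out[d] <- mean(values[lo:d])
  }
  out
}

# First DOY >= start whose trailing running mean is below `threshold`
# (strictly, or <= when inclusive); NA if none.
naive_first_below <- function(values, window, start, threshold,
                              inclusive = FALSE) {
  n <- length(values)
  for (d in start:n) {
    lo <- max(1L, d - window + 1L)
    m <- mean(values[lo:d])
    if ((inclusive && m <= threshold) || (!inclusive && m < threshold)) {
      return(d)
    }
  }
  NA_integer_
}

# A random but season-shaped daily series (one non-leap year).
random_series <- function(t_avg = runif(1, -10, 20),
                          amplitude = runif(1, 10, 25),
                          noise_sd = runif(1, 0, 3),
                          n_days = 365L) {
  d <- seq_len(n_days)
  t_avg + amplitude * cos(2 * pi * (d - 200) / 365) +
    rnorm(n_days, sd = noise_sd)
}

# Small zero/low-noise synthetic fixture shared across tests.
small_fixture <- function(biomes_idx = 1L, n_pixels = 30L,
                          years = 2001:2002, egs_noise_sd = 0,
                          seed = 42L, ...) {
  cfg <- synthetic_config(
    n_pixels_per_biome = n_pixels,
    biomes = default_biome_ranges()[biomes_idx, , drop = FALSE],
    egs_noise_sd = egs_noise_sd, years = years, seed = seed, ...)
  generate_dataset(cfg)
}

# One-biome parameter-recovery run: generate a fixture with known truth and
# refit by grid search on all pixels.
recovery_fit <- function(biome_name, t_lo, t_hi, n_pixels = 500L,
                         years = 2001:2003, egs_noise_sd = 0, seed = 101L) {
  rng <- data.frame(biome = biome_name, t_avg_min = t_lo, t_avg_max = t_hi)
  cfg <- synthetic_config(n_pixels_per_biome = n_pixels, biomes = rng,
                          egs_noise_sd = egs_noise_sd, years = years,
                          seed = seed)
  ds <- generate_dataset(cfg)
  py <- prepare_pixel_years(ds$pixels, ds$temperature)
  list(fit = fit_biome(py), truth = ds$truth$params_by_biome,
       dataset = ds, py = py)
}
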