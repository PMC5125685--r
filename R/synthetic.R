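#' Reference threshold parameters per biome
#'
#' The per-biome adaptive-threshold parameters `(a, b)` calibrated against
#' satellite-observed Northern Hemisphere senescence dates. They serve as
#' the package's reference parameter set and as the default ground truth of
#' the synthetic generator, making parameter recovery against them the
#' package's core self-check.
#'
#' @return Data frame with columns `biome`, `a` (degC), `b`
#'   (dimensionless).
#' @export
default_biome_params <- function() {
  data.frame(
    biome = c("evergreen_needleleaf_forest", "deciduous_needleleaf_forest",
              "deciduous_broadleaf_forest", "mixed_forest",
              "closed_shrubland", "open_shrubland", "woody_savanna",
              "savanna", "grassland", "permanent_wetland"),
    a = c(8, 8, 8, 8, 8, 7, 8, 8, 7, 8),
    b = c(0.272, 0.038, 0.02, 0.02, 0.02, 0.02, 0.02, 0.238, 0.02, 0.02)
  )
}

#' Default mean-annual-temperature ranges per biome
#'
#' Plausible Northern Hemisphere climatological ranges for each IGBP biome,
#' chosen so simulated critical thresholds land in the observed 7-9 degC
#' band. These are configuration, not code: pass a modified table to
#' [synthetic_config()] to change them.
#'
#' @return Data frame with columns `biome`, `t_avg_min`, `t_avg_max`
#'   (degC).
#' @export
default_biome_ranges <- function() {
  data.frame(
    biome = c("evergreen_needleleaf_forest", "deciduous_needleleaf_forest",
              "deciduous_broadleaf_forest", "mixed_forest",
              "closed_shrubland", "open_shrubland", "woody_savanna",
              "savanna", "grassland", "permanent_wetland"),
    t_avg_min = c(-10, -15, 0, -5, 0, -5, 5, 15, -5, -5),
    t_avg_max = c(15, 5, 15, 15, 20, 20, 22, 25, 20, 20)
  )
}

#' Configuration of the synthetic gridded dataset
#'
#' Bundles and validates every knob of the generator. Daily temperature is
#' a sinusoidal annual cycle plus AR(1) noise; observed end-of-season dates
#' are generated from the adaptive-threshold model with known per-biome
#' parameters plus rounded Gaussian observation noise, so the ground truth
#' of every fixture is known exactly.
#'
#' The per-pixel seasonal amplitude is `max(U(amplitude_range),
#' |t_avg - 8| + 4)` degC: a continentality proxy that guarantees the
#' annual cycle passes through the critical-threshold band (roughly
#' 7-9 degC) after midsummer for every pixel, while keeping the autumn
#' cooling rate `2*pi*A/365` within 0.05-0.5 degC/day over the default
#' `t_avg` ranges.
#'
#' @param n_pixels_per_biome Pixels per biome (default 50).
#' @param biomes Data frame of biomes and `t_avg` ranges
#'   (default [default_biome_ranges()]).
#' @param params Ground-truth threshold parameters per biome
#'   (default [default_biome_params()]).
#' @param amplitude_range Range of the uniform seasonal-amplitude draw in
#'   degC (default `c(12, 18)`).
#' @param peak_doy Day-of-year of the warmest day (default 200).
#' @param ar1_coefficient AR(1) coefficient of daily noise in `[0, 1)`
#'   (default 0.7).
#' @param daily_noise_sd Innovation standard deviation of the AR(1) daily
#'   noise in degC (default 2).
#' @param egs_noise_sd Standard deviation of the Gaussian observation noise
#'   on end-of-season dates in days, rounded to whole days and clipped to
#'   `[183, 365]` (default 5, a typical satellite retrieval uncertainty).
#' @param years Calendar years to simulate (default `2001:2003`).
#' @param trend_days_per_year Imposed warming-driven shift of the
#'   end-of-season date in days per year (default 0). Implemented as a
#'   per-pixel linear warming of the daily series, scaled to the local
#'   autumn cooling rate at the expected crossing and centred on the middle
#'   year so the pooled mean annual temperature is unchanged.
#' @param search_start,window Model settings used to generate observed
#'   dates (defaults 183 and 10).
#' @param no_crossing `"regenerate"` (default) redraws a pixel whose series
#'   never crosses its threshold (up to `max_regen` attempts); `"error"`
#'   aborts.
#' @param max_regen Maximum redraws per pixel (default 20).
#' @param seed RNG seed (default 1); the whole fixture is deterministic
#'   given the config.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pixels_per_biome = 50L,
                             biomes = default_biome_ranges(),
                             params = default_biome_params(),
                             amplitude_range = c(12, 18),
                             peak_doy = 200L,
                             ar1_coefficient = 0.7,
                             daily_noise_sd = 2,
                             egs_noise_sd = 5,
                             years = 2001:2003,
                             trend_days_per_year = 0,
                             search_start = 183L,
                             window = 10L,
                             no_crossing = c("regenerate", "error"),
                             max_regen = 20L,
                             seed = 1L) {
  stopifnot(is.data.frame(biomes),
            all(c("biome", "t_avg_min", "t_avg_max") %in% names(biomes)),
            is.data.frame(params),
            all(c("biome", "a", "b") %in% names(params)))
  if (any(biomes$t_avg_min >= biomes$t_avg_max)) {
    stop("every biome needs t_avg_min < t_avg_max", call. = FALSE)
  }
  if (!all(biomes$biome %in% params$biome)) {
    stop("missing ground-truth parameters for biome(s): ",
         paste(setdiff(biomes$biome, params$biome), collapse = ", "),
         call. = FALSE)
  }
  if (length(amplitude_range) != 2L || amplitude_range[1] <= 0 ||
      diff(amplitude_range) < 0) {
    stop("`amplitude_range` must be an increasing positive pair",
         call. = FALSE)
  }
  if (ar1_coefficient < 0 || ar1_coefficient >= 1) {
    stop("`ar1_coefficient` must be in [0, 1)", call. = FALSE)
  }
  stopifnot(n_pixels_per_biome >= 1, daily_noise_sd >= 0, egs_noise_sd >= 0,
            length(years) >= 1)
  structure(
    list(n_pixels_per_biome = as.integer(n_pixels_per_biome),
         biomes = biomes, params = params,
         amplitude_range = amplitude_range, peak_doy = as.integer(peak_doy),
         ar1_coefficient = ar1_coefficient,
         daily_noise_sd = daily_noise_sd, egs_noise_sd = egs_noise_sd,
         years = as.integer(years),
         trend_days_per_year = trend_days_per_year,
         search_start = as.integer(search_start),
         window = as.integer(window),
         no_crossing = match.arg(no_crossing),
         max_regen = as.integer(max_regen),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Simulate daily temperature for one pixel
#'
#' One pixel's daily mean temperature over a span of years:
#' `T(d) = t_avg + A * cos(2*pi*(d - peak_doy)/365) + warming + eps(d)`,
#' where `eps` is an AR(1) process (continuous across year boundaries) with
#' the given coefficient and innovation standard deviation, and `warming`
#' is an optional linear offset per year centred on the middle year.
#'
#' This function draws from the current RNG stream; seed it (or use
#' [generate_dataset()], which seeds everything from its config) for
#' reproducibility.
#'
#' @param t_avg Target mean annual temperature in degC.
#' @param amplitude Seasonal amplitude in degC (> 0).
#' @param years Calendar years.
#' @param peak_doy Day-of-year of the warmest day.
#' @param ar1_coefficient,daily_noise_sd AR(1) noise parameters.
#' @param warming_per_year Linear warming in degC per year (applied as an
#'   offset `warming_per_year * (year_index - (n+1)/2)`).
#' @return Named list of daily temperature vectors, one per year.
#' @export
generate_temperature <- function(t_avg, amplitude, years = 2001:2003,
                                 peak_doy = 200L, ar1_coefficient = 0.7,
                                 daily_noise_sd = 2,
                                 warming_per_year = 0) {
  if (amplitude <= 0) stop("`amplitude` must be positive", call. = FALSE)
  nd <- days_in_year(years)
  total <- sum(nd)
  eps <- if (daily_noise_sd > 0) {
    as.numeric(filter(rnorm(total, sd = daily_noise_sd),
                      ar1_coefficient, method = "recursive"))
  } else {
    numeric(total)
  }
  offsets <- warming_per_year * (seq_along(years) - (length(years) + 1) / 2)
  out <- vector("list", length(years))
  pos <- 0L
  for (i in seq_along(years)) {
    d <- seq_len(nd[i])
    season <- amplitude * cos(2 * pi * (d - peak_doy) / 365)
    out[[i]] <- t_avg + season + offsets[i] + eps[pos + d]
    pos <- pos + nd[i]
  }
  names(out) <- as.character(years)
  out
}

#' Simulate observed end-of-season dates for one pixel
#'
#' The model-predicted senescence date for each year (adaptive threshold at
#' the pixel's pooled climatological mean annual temperature) plus rounded
#' Gaussian observation noise, clipped to `[183, 365]`. With
#' `egs_noise_sd = 0` the output is exactly the model prediction.
#'
#' @param series_by_year Named list of daily temperature vectors.
#' @param a,b Ground-truth threshold parameters.
#' @param egs_noise_sd Observation noise sd in days.
#' @param search_start,window Model settings.
#' @return Integer vector of observed days-of-year (one per year), or
#'   `NULL` if the model never crosses the threshold in some year.
#' @export
generate_observed_egs <- function(series_by_year, a, b, egs_noise_sd = 0,
                                  search_start = 183L, window = 10L) {
  cl <- pixel_climate(series_by_year)
  th <- tcrit(a, b, cl$t_avg)
  pred <- unname(vapply(series_by_year, predict_egs_novel, integer(1),
                        threshold = th, search_start = search_start,
                        window = window))
  if (anyNA(pred)) return(NULL)
  if (egs_noise_sd > 0) {
    pred <- as.integer(round(pred + rnorm(length(pred), sd = egs_noise_sd)))
  }
  pmin(pmax(pred, 183L), 365L)
}

#' Generate a complete synthetic gridded dataset
#'
#' Draws, per biome, pixels with uniform mean annual temperature, simulates
#' their daily series, derives the pooled climatology, and generates
#' observed end-of-season dates from the adaptive-threshold model with the
#' configured ground-truth parameters. Pixels whose series never crosses
#' their threshold (possible in the noise tails) are redrawn. The result is
#' deterministic given the config.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_dataset`:
#'   * `pixels`: data frame, one row per pixel-year (`pixel_id`, `lat`,
#'     `lon`, `biome`, `t_avg` — realised pooled climatology, `year`,
#'     `egs_doy_observed`);
#'   * `temperature`: long data frame (`pixel_id`, `year`, `doy`, `tmean`);
#'   * `truth`: ground-truth parameters and a config echo.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    pix_rows <- list()
    temp_rows <- list()
    counter <- 0L
    for (k in seq_len(nrow(config$biomes))) {
      bio <- config$biomes$biome[[k]]
      pr <- config$params[config$params$biome == bio, ]
      for (j in seq_len(config$n_pixels_per_biome)) {
        counter <- counter + 1L
        pid <- sprintf("px%05d", counter)
        done <- FALSE
        for (attempt in seq_len(config$max_regen + 1L)) {
          t_avg_target <- runif(1, config$biomes$t_avg_min[[k]],
                                config$biomes$t_avg_max[[k]])
          amplitude <- max(runif(1, config$amplitude_range[1],
                                 config$amplitude_range[2]),
                           abs(t_avg_target - 8) + 4)
          warming <- trend_warming_rate(config$trend_days_per_year,
                                        t_avg_target, amplitude,
                                        pr$a, pr$b)
          series <- generate_temperature(
            t_avg_target, amplitude, years = config$years,
            peak_doy = config$peak_doy,
            ar1_coefficient = config$ar1_coefficient,
            daily_noise_sd = config$daily_noise_sd,
            warming_per_year = warming)
          obs <- generate_observed_egs(
            series, pr$a, pr$b, egs_noise_sd = config$egs_noise_sd,
            search_start = config$search_start, window = config$window)
          if (!is.null(obs)) {
            done <- TRUE
            break
          }
          if (config$no_crossing == "error") {
            stop("pixel '", pid, "' (", bio,
                 ") never crosses its threshold", call. = FALSE)
          }
        }
        if (!done) {
          stop("pixel '", pid, "' (", bio, ") produced no crossing after ",
               config$max_regen + 1L, " draws", call. = FALSE)
        }
        cl <- pixel_climate(series)
        lat <- runif(1, 30, 70)
        lon <- runif(1, -180, 180)
        pix_rows[[counter]] <- data.frame(
          pixel_id = pid, lat = lat, lon = lon, biome = bio,
          t_avg = cl$t_avg, year = config$years,
          egs_doy_observed = obs)
        temp_rows[[counter]] <- data.frame(
          pixel_id = pid,
          year = rep(config$years, times = days_in_year(config$years)),
          doy = unlist(lapply(days_in_year(config$years), seq_len),
                       use.names = FALSE),
          tmean = unlist(series, use.names = FALSE))
      }
    }
    structure(
      list(pixels = do.call(rbind, pix_rows),
           temperature = do.call(rbind, temp_rows),
           truth = list(params_by_biome =
                          config$params[config$params$biome %in%
                                          config$biomes$biome, ],
                        config = config)),
      class = "synthetic_dataset"
    )
  })
}

# Internal: warming rate (degC/yr) that shifts the crossing by `trend`
# days/yr at first order: the local cooling rate of the seasonal cycle at
# the expected crossing temperature is 2*pi*A/365 * |sin(theta*)| with
# cos(theta*) = (tcrit - t_avg)/A.
trend_warming_rate <- function(trend, t_avg, amplitude, a, b) {
  if (trend == 0) return(0)
  c_star <- (tcrit(a, b, t_avg) - t_avg) / amplitude
  c_star <- min(max(c_star, -1), 1)
  sin_star <- max(sqrt(1 - c_star^2), 0.2)  # guard grazing crossings
  trend * (2 * pi * amplitude / 365) * sin_star
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic dataset: %d pixel-years, %d pixels, %d biome(s), years %s-%s (seed %d)\n",
              nrow(x$pixels), length(unique(x$pixels$pixel_id)),
              length(unique(x$pixels$biome)),
              min(x$pixels$year), max(x$pixels$year),
              x$truth$config$seed))
  invisible(x)
}
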