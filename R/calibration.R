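#' Random calibration/validation split of pixels
#'
#' Randomly assigns pixels to a calibration set and a validation set, the
#' standard protocol for satellite-calibrated phenology models: parameters
#' are estimated on one half of the pixels and skill is reported on the
#' held-out half. The split is deterministic given `seed` and leaves the
#' caller's RNG state untouched. The calibration set size is
#' `round(fraction * n)` with halves rounded up.
#'
#' @param pixel_ids Vector of unique pixel identifiers.
#' @param fraction Proportion assigned to calibration (default 0.5).
#' @param seed RNG seed (required, and recorded in the result).
#' @return A list of class `calibration_split` with elements
#'   `calibration_pixels`, `validation_pixels`, `seed`, `fraction`.
#' @export
split_pixels <- function(pixel_ids, fraction = 0.5, seed) {
  if (anyDuplicated(pixel_ids)) {
    stop("`pixel_ids` must be unique", call. = FALSE)
  }
  n <- length(pixel_ids)
  if (n < 2L) {
    stop("need at least 2 pixels to split", call. = FALSE)
  }
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  }
  n_cal <- as.integer(floor(fraction * n + 0.5))  # round half up
  cal_idx <- with_seed(seed, sample.int(n, n_cal))
  structure(
    list(calibration_pixels = pixel_ids[sort(cal_idx)],
         validation_pixels = pixel_ids[-sort(cal_idx)],
         seed = seed, fraction = fraction),
    class = "calibration_split"
  )
}

#' @export
print.calibration_split <- function(x, ...) {
  cat(sprintf("calibration split: %d calibration / %d validation pixels (seed %s, fraction %g)\n",
              length(x$calibration_pixels), length(x$validation_pixels),
              format(x$seed), x$fraction))
  invisible(x)
}

#' Assemble pixel-years for calibration and prediction
#'
#' Joins the pixel table (one row per pixel-year with its observed
#' end-of-season date) with the per-pixel daily temperature record, computes
#' per-pixel climatologies and pre-smooths each year's series so that
#' threshold predictions for many candidate parameter values are cheap.
#' Internally the smoothed July-onward segment of each pixel-year is reduced
#' to its prefix minimum, which makes the first-crossing day a simple count
#' of values above a candidate threshold.
#'
#' @param pixels Data frame with columns `pixel_id`, `biome`, `year`,
#'   `egs_doy_observed` (observed day may be `NA` when only predictions are
#'   needed).
#' @param temperature Long data frame with columns `pixel_id`, `year`,
#'   `doy`, `tmean`, or a nested list as returned by
#'   [temperature_store()].
#' @param search_start First day-of-year eligible for senescence
#'   (default 183).
#' @param window Running-mean window in days (default 10).
#' @param tavg_mode `"climatology"` (default) uses the multi-year pooled
#'   mean annual temperature per pixel; `"per_year"` uses each year's own
#'   mean.
#' @return An object of class `egs_pixel_years`.
#' @export
prepare_pixel_years <- function(pixels, temperature, search_start = 183L,
                                window = 10L,
                                tavg_mode = c("climatology", "per_year")) {
  tavg_mode <- match.arg(tavg_mode)
  store <- temperature_store(temperature)
  need <- c("pixel_id", "biome", "year")
  if (!all(need %in% names(pixels))) {
    stop("`pixels` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"egs_doy_observed" %in% names(pixels)) {
    pixels$egs_doy_observed <- NA_integer_
  }
  search_start <- as.integer(search_start)
  m <- nrow(pixels)
  if (m == 0L) stop("`pixels` has no rows", call. = FALSE)

  pids <- unique(pixels$pixel_id)
  climates <- lapply(pids, function(pid) {
    yrs <- store[[pid]]
    if (is.null(yrs)) {
      stop("no temperature record for pixel '", pid, "'", call. = FALSE)
    }
    pixel_climate(yrs)
  })
  names(climates) <- pids

  max_search <- 366L - search_start + 1L
  pm <- matrix(-Inf, nrow = m, ncol = max_search)
  n_search <- integer(m)
  t_avg <- numeric(m)
  t_cold <- numeric(m)
  for (i in seq_len(m)) {
    pid <- pixels$pixel_id[[i]]
    yr <- pixels$year[[i]]
    series <- store[[pid]][[as.character(yr)]]
    if (is.null(series)) {
      stop("pixel '", pid, "' has no temperature for year ", yr,
           call. = FALSE)
    }
    validate_series(series, yr,
                    what = sprintf("temperature for pixel '%s' year %s",
                                   pid, yr))
    sm <- running_mean(series, window)
    seg <- sm[search_start:length(sm)]
    k <- length(seg)
    pm[i, seq_len(k)] <- cummin(seg)
    n_search[[i]] <- k
    cl <- climates[[pid]]
    t_avg[[i]] <- if (tavg_mode == "climatology") cl$t_avg else mean(series)
    t_cold[[i]] <- cl$t_coldest_month
  }
  structure(
    list(pm = pm, n_search = n_search, t_avg = t_avg,
         t_coldest_month = t_cold,
         observed = as.integer(pixels$egs_doy_observed),
         pixel_id = pixels$pixel_id, year = pixels$year,
         biome = pixels$biome, climates = climates,
         search_start = search_start, window = as.integer(window),
         tavg_mode = tavg_mode),
    class = "egs_pixel_years"
  )
}

#' @export
print.egs_pixel_years <- function(x, ...) {
  cat(sprintf("%d pixel-years (%d pixels, %d biome(s)); search from DOY %d, %d-day window\n",
              length(x$observed), length(unique(x$pixel_id)),
              length(unique(x$biome)), x$search_start, x$window))
  invisible(x)
}

# Internal: vectorised first-crossing prediction for prepared pixel-years.
# `threshold` is recycled to one value per pixel-year. Returns integer DOY
# with NA for no-crossing (sentinel) pixel-years.
predict_from_prepared <- function(py, threshold) {
  th <- rep_len(threshold, nrow(py$pm))
  cnt <- rowSums(py$pm >= th)
  doy <- py$search_start + as.integer(cnt)
  doy[cnt >= py$n_search] <- NA_integer_
  doy
}

#' Predict end-of-season dates for prepared pixel-years
#'
#' Applies one of the phenology rules to every pixel-year of a prepared
#' dataset. For the adaptive model the threshold is `a + b * t_avg` with
#' biome-specific parameters; for the IBIS baseline the biome is mapped to
#' the tree or the grass/shrub rule.
#'
#' @param py An `egs_pixel_years` object from [prepare_pixel_years()].
#' @param model `"novel"` (adaptive threshold) or `"ibis"` (baseline rules).
#' @param params For `model = "novel"`: data frame with columns `biome`,
#'   `a`, `b` covering every biome present (see [default_biome_params()]).
#' @return Integer vector of predicted days-of-year (`NA` = no senescence),
#'   aligned with the pixel-years of `py`.
#' @export
predict_egs <- function(py, model = c("novel", "ibis"), params = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(py, "egs_pixel_years"))
  if (model == "novel") {
    if (is.null(params)) {
      stop("`params` (biome, a, b) is required for the adaptive model",
           call. = FALSE)
    }
    idx <- match(py$biome, params$biome)
    if (anyNA(idx)) {
      stop("missing parameters for biome(s): ",
           paste(unique(py$biome[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    th <- tcrit(params$a[idx], params$b[idx], py$t_avg)
    predict_from_prepared(py, th)
  } else {
    grassy <- py$biome %in% ibis_grass_biomes()
    out <- integer(length(py$observed))
    # grass/shrub rule is an inclusive <= 0 trigger; emulate via strict
    # threshold at the smallest increment above 0
    th <- ifelse(grassy, 0, pmax(0, py$t_coldest_month + 5))
    cnt_strict <- rowSums(py$pm >= th)
    cnt_incl <- rowSums(py$pm > th)   # counts days with pm > th: <= trigger
    cnt <- ifelse(grassy, cnt_incl, cnt_strict)
    doy <- py$search_start + as.integer(cnt)
    doy[cnt >= py$n_search] <- NA_integer_
    doy
  }
}

#' Biomes handled by the IBIS grass/shrub rule
#'
#' The baseline rules distinguish trees from grasses and shrubs; this is
#' the package's mapping of IGBP classes to the grass/shrub rule (all other
#' classes use the tree rule).
#' @return Character vector of biome labels.
#' @export
ibis_grass_biomes <- function() {
  c("grassland", "closed_shrubland", "open_shrubland", "savanna")
}

#' Error sum of squares from paired predictions and observations
#'
#' The calibration objective contribution of a set of pixel-years:
#' `sum((predicted - observed)^2)` in days squared. Sentinel (no-crossing)
#' predictions contribute a censored penalty `(365 - observed)^2` by
#' default, which keeps the objective finite and pushes parameters toward
#' producing a crossing; alternatively they can be dropped.
#'
#' @param predicted Integer predictions (`NA` = sentinel).
#' @param observed Integer observed days-of-year.
#' @param sentinel `"censored"` (default) or `"drop"`.
#' @return ESS in days squared.
#' @export
ess_from_predictions <- function(predicted, observed,
                                 sentinel = c("censored", "drop")) {
  sentinel <- match.arg(sentinel)
  if (length(predicted) != length(observed) || length(observed) == 0L) {
    stop("`predicted` and `observed` must be non-empty and equal length",
         call. = FALSE)
  }
  s <- is.na(predicted)
  ess <- sum((predicted[!s] - observed[!s])^2)
  if (sentinel == "censored" && any(s)) {
    ess <- ess + sum((365 - observed[s])^2)
  }
  ess
}

#' Calibration objective for one candidate parameter pair
#'
#' Evaluates the error sum of squares between model-predicted and observed
#' end-of-season dates over a set of prepared pixel-years, for threshold
#' parameters `(a, b)`.
#'
#' @param a,b Candidate threshold parameters (see [tcrit()]).
#' @param py An `egs_pixel_years` object with observed dates.
#' @param sentinel Sentinel handling, see [ess_from_predictions()].
#' @return ESS in days squared.
#' @export
ess_objective <- function(a, b, py, sentinel = c("censored", "drop")) {
  stopifnot(inherits(py, "egs_pixel_years"))
  if (anyNA(py$observed)) {
    stop("all pixel-years must have an observed EGS date", call. = FALSE)
  }
  pred <- predict_from_prepared(py, tcrit(a, b, py$t_avg))
  ess_from_predictions(pred, py$observed, sentinel = match.arg(sentinel))
}

# Internal: ESS for a whole grid of candidates; returns data.frame.
ess_grid <- function(a_vals, b_vals, py, sentinel) {
  grid <- expand.grid(a = a_vals, b = b_vals, KEEP.OUT.ATTRS = FALSE)
  obs <- py$observed
  grid$ess <- vapply(seq_len(nrow(grid)), function(i) {
    pred <- predict_from_prepared(py, tcrit(grid$a[i], grid$b[i], py$t_avg))
    ess_from_predictions(pred, obs, sentinel = sentinel)
  }, numeric(1))
  grid
}

# Internal: grid covering [center - span, center + span] at `step`,
# clipped to box.
refine_seq <- function(center, span, step, box) {
  lo <- max(box[1], center - span)
  hi <- min(box[2], center + span)
  unique(c(seq(lo, hi, by = step), hi))
}

#' Fit the threshold parameters for one biome
#'
#' Minimises the error sum of squares between predicted and observed
#' end-of-season dates over `(a, b)` by a coarse-to-fine grid search.
#' Because predictions are integer days-of-year, the objective is piecewise
#' constant in the parameters and derivative-based optimisers are ill-posed;
#' a nested grid whose finest resolution (a: 0.05 degC, b: 0.002) matches
#' the precision to which threshold parameters are conventionally reported
#' is both robust and exact to that resolution. Ties on the finest grid are
#' broken by the centroid of the minimising set.
#'
#' @param py Prepared pixel-years for one biome (observed dates required).
#' @param search_box List with numeric ranges `a` (degC, default
#'   `c(-20, 20)`) and `b` (default `c(-1, 1)`).
#' @param steps List of per-level grid resolutions, finest last (defaults:
#'   `a` 1, 0.2, 0.05 degC; `b` 0.05, 0.01, 0.002).
#' @param sentinel Sentinel handling, see [ess_from_predictions()].
#' @return A list of class `calibration_result`: `biome`, `a`, `b`, `ess`,
#'   `n_pixel_years`, `n_sentinel`, `search_trace` (best candidate per
#'   level), and `warnings`.
#' @export
fit_biome <- function(py,
                      search_box = list(a = c(-20, 20), b = c(-1, 1)),
                      steps = list(a = c(1, 0.2, 0.05),
                                   b = c(0.05, 0.01, 0.002)),
                      sentinel = c("censored", "drop")) {
  sentinel <- match.arg(sentinel)
  stopifnot(inherits(py, "egs_pixel_years"))
  n <- length(py$observed)
  if (n < 10L) {
    stop("need at least 10 pixel-years to calibrate (got ", n, ")",
         call. = FALSE)
  }
  if (anyNA(py$observed)) {
    stop("all pixel-years must have an observed EGS date", call. = FALSE)
  }
  warns <- character(0)
  if (diff(range(py$t_avg)) <= 1) {
    warns <- c(warns, paste0(
      "t_avg spans <= 1 degC: intercept and slope are not jointly ",
      "identifiable"))
    warning(warns[[length(warns)]], call. = FALSE)
  }
  n_levels <- length(steps$a)
  stopifnot(n_levels == length(steps$b), n_levels >= 1L)

  a_vals <- seq(search_box$a[1], search_box$a[2], by = steps$a[1])
  b_vals <- seq(search_box$b[1], search_box$b[2], by = steps$b[1])
  trace <- vector("list", n_levels)
  best <- NULL
  for (lev in seq_len(n_levels)) {
    if (lev > 1L) {
      a_vals <- refine_seq(best$a, steps$a[lev - 1L], steps$a[lev],
                           search_box$a)
      b_vals <- refine_seq(best$b, steps$b[lev - 1L], steps$b[lev],
                           search_box$b)
    }
    grid <- ess_grid(a_vals, b_vals, py, sentinel)
    i_best <- which.min(grid$ess)
    best <- grid[i_best, ]
    trace[[lev]] <- data.frame(level = lev, a = best$a, b = best$b,
                               ess = best$ess,
                               n_candidates = nrow(grid))
    if (lev == n_levels) {
      # centroid of the minimising set breaks plateau ties symmetrically
      minset <- grid[grid$ess == best$ess, , drop = FALSE]
      a_c <- mean(minset$a)
      b_c <- mean(minset$b)
      ess_c <- ess_objective(a_c, b_c, py, sentinel = sentinel)
      if (ess_c <= best$ess) {
        best <- data.frame(a = a_c, b = b_c, ess = ess_c)
      }
    }
  }
  pred <- predict_from_prepared(py, tcrit(best$a, best$b, py$t_avg))
  structure(
    list(biome = if (length(unique(py$biome)) == 1L) py$biome[[1L]] else NA,
         a = best$a, b = best$b, ess = best$ess,
         n_pixel_years = n, n_sentinel = sum(is.na(pred)),
         search_trace = do.call(rbind, trace),
         search_box = search_box, steps = steps, sentinel = sentinel,
         warnings = warns),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibrated threshold parameters for '%s': a = %.3f degC, b = %.3f\n",
              x$biome, x$a, x$b))
  cat(sprintf("  ESS = %.1f days^2 over %d pixel-years (%d without predicted crossing)\n",
              x$ess, x$n_pixel_years, x$n_sentinel))
  if (length(x$warnings)) cat("  warning:", x$warnings, sep = "\n  ")
  invisible(x)
}

#' Calibrate threshold parameters for every biome in a dataset
#'
#' Splits the pixels of each biome into calibration and validation halves,
#' fits `(a, b)` on the calibration pixels by [fit_biome()], and returns
#' one result per biome. Biomes with too few calibration pixel-years are
#' skipped with a warning. The split is drawn independently per biome
#' (deterministic given `split_seed`).
#'
#' @param pixels Pixel table (one row per pixel-year) with columns
#'   `pixel_id`, `biome`, `year`, `egs_doy_observed`.
#' @param temperature Long temperature table or [temperature_store()].
#' @param split_seed Seed for the random pixel split (required; recorded in
#'   the results). Set `fraction = 1` semantics via `split = NULL` is not
#'   offered: calibration always holds out pixels unless `use_split =
#'   FALSE`.
#' @param fraction Calibration fraction (default 0.5).
#' @param use_split If `FALSE`, fit on all pixels (no hold-out); used for
#'   controlled recovery experiments.
#' @param search_start,window,tavg_mode Passed to [prepare_pixel_years()].
#' @param search_box,steps,sentinel Passed to [fit_biome()].
#' @return A named list of `calibration_result` objects (class
#'   `calibration_set`), with the per-biome splits in
#'   `attr(, "splits")`.
#' @export
calibrate_all <- function(pixels, temperature, split_seed, fraction = 0.5,
                          use_split = TRUE, search_start = 183L,
                          window = 10L,
                          tavg_mode = c("climatology", "per_year"),
                          search_box = list(a = c(-20, 20), b = c(-1, 1)),
                          steps = list(a = c(1, 0.2, 0.05),
                                       b = c(0.05, 0.01, 0.002)),
                          sentinel = c("censored", "drop")) {
  tavg_mode <- match.arg(tavg_mode)
  sentinel <- match.arg(sentinel)
  store <- temperature_store(temperature)
  results <- list()
  splits <- list()
  for (bio in sort(unique(pixels$biome))) {
    rows <- pixels[pixels$biome == bio, , drop = FALSE]
    pids <- sort(unique(rows$pixel_id))
    if (use_split) {
      if (length(pids) < 2L) {
        warning("biome '", bio, "' has fewer than 2 pixels; skipped",
                call. = FALSE)
        next
      }
      sp <- split_pixels(pids, fraction, seed = split_seed)
      splits[[bio]] <- sp
      rows <- rows[rows$pixel_id %in% sp$calibration_pixels, , drop = FALSE]
    }
    res <- tryCatch({
      py <- prepare_pixel_years(rows, store, search_start = search_start,
                                window = window, tavg_mode = tavg_mode)
      fit_biome(py, search_box = search_box, steps = steps,
                sentinel = sentinel)
    }, error = function(e) {
      warning("biome '", bio, "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      res$split_seed <- if (use_split) split_seed else NA
      results[[bio]] <- res
    }
  }
  structure(results, class = "calibration_set", splits = splits)
}

#' Tabulate a set of calibration results
#'
#' Flattens a [calibrate_all()] result into the conventional per-biome
#' parameter table (biome, a, b) plus provenance columns.
#'
#' @param results A `calibration_set` or list of `calibration_result`s.
#' @return Data frame with columns `biome`, `a`, `b`, `ess`,
#'   `n_pixel_years`, `n_sentinel`, `split_seed`.
#' @export
params_table <- function(results) {
  do.call(rbind, lapply(unname(results), function(r) {
    data.frame(biome = r$biome, a = r$a, b = r$b, ess = r$ess,
               n_pixel_years = r$n_pixel_years, n_sentinel = r$n_sentinel,
               split_seed = if (is.null(r$split_seed)) NA else r$split_seed)
  }))
}
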