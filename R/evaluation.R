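#' Coefficient of determination between observed and predicted dates
#'
#' The headline agreement statistic: the squared Pearson correlation
#' between observed and predicted end-of-season days. The sum-of-squares
#' form `1 - SSE/SST` is also available; squared correlation is the
#' dominant convention in phenology validation and is the default.
#' Sentinel (`NA`) predictions are excluded pairwise.
#'
#' @param observed,predicted Numeric vectors of days-of-year.
#' @param method `"pearson"` (default) or `"ss"` (`1 - SSE/SST`).
#' @return Dimensionless; `NA` with a classed warning
#'   (`egsmodel_undefined_metric`) when fewer than 3 pairs remain or either
#'   vector has zero variance.
#' @export
r_squared <- function(observed, predicted, method = c("pearson", "ss")) {
  method <- match.arg(method)
  p <- complete_pairs(observed, predicted)
  if (nrow(p) < 3L) {
    return(undefined_metric("r_squared needs at least 3 complete pairs"))
  }
  if (stats::var(p$obs) == 0 ||
      (method == "pearson" && stats::var(p$pred) == 0)) {
    return(undefined_metric("r_squared undefined for zero-variance input"))
  }
  if (method == "pearson") {
    cor(p$obs, p$pred)^2
  } else {
    1 - sum((p$obs - p$pred)^2) / sum((p$obs - mean(p$obs))^2)
  }
}

complete_pairs <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  }
  keep <- !is.na(observed) & !is.na(predicted)
  data.frame(obs = as.numeric(observed[keep]),
             pred = as.numeric(predicted[keep]))
}

#' Root mean square error of predicted dates
#'
#' @inheritParams r_squared
#' @return RMSE in days over non-sentinel pairs; `NA` with an
#'   `egsmodel_undefined_metric` warning when no pair is complete.
#' @export
rmse <- function(observed, predicted) {
  p <- complete_pairs(observed, predicted)
  if (nrow(p) == 0L) return(undefined_metric("rmse of all-sentinel input"))
  sqrt(mean((p$pred - p$obs)^2))
}

#' Mean absolute error of predicted dates
#'
#' The per-pixel mean absolute difference between modelled and observed
#' end-of-season dates, in days.
#'
#' @inheritParams r_squared
#' @return MAE in days; `NA` with an `egsmodel_undefined_metric` warning
#'   when no pair is complete.
#' @export
mean_absolute_error <- function(observed, predicted) {
  p <- complete_pairs(observed, predicted)
  if (nrow(p) == 0L) return(undefined_metric("MAE of all-sentinel input"))
  mean(abs(p$pred - p$obs))
}

#' Fraction of pixels predicted within k days of the observation
#'
#' @inheritParams r_squared
#' @param k Tolerance in days (vectorised, `k >= 0`).
#' @return Fraction of non-sentinel pairs with
#'   `|predicted - observed| <= k` for each `k`.
#' @export
cumulative_within <- function(observed, predicted, k) {
  if (any(k < 0)) stop("`k` must be non-negative", call. = FALSE)
  p <- complete_pairs(observed, predicted)
  if (nrow(p) == 0L) {
    return(undefined_metric("cumulative agreement of all-sentinel input"))
  }
  d <- abs(p$pred - p$obs)
  vapply(k, function(kk) mean(d <= kk), numeric(1))
}

#' Cumulative within-k-day agreement curve
#'
#' Evaluates [cumulative_within()] at integer tolerances `k = 0..k_max`,
#' the curve used to report "x% of pixels within 10 days".
#'
#' @inheritParams r_squared
#' @param k_max Largest tolerance in days (default 90).
#' @return Data frame with columns `k` and `fraction`.
#' @export
cumulative_curve <- function(observed, predicted, k_max = 90L) {
  k <- 0:k_max
  data.frame(k = k, fraction = cumulative_within(observed, predicted, k))
}

#' Linear regression of empirical thresholds on mean annual temperature
#'
#' Ordinary least squares of the per-pixel empirical temperature threshold
#' (the running-mean temperature at the observed end-of-season date, see
#' [observed_threshold()]) on the per-pixel mean annual temperature. On
#' data generated by the adaptive-threshold model this recovers the
#' threshold parameters `(a, b)` directly.
#'
#' @param thresholds Empirical thresholds in degC, one per pixel(-year).
#' @param t_avg Mean annual temperatures in degC.
#' @return List with `intercept` (degC), `slope` (dimensionless), `r`
#'   (Pearson correlation), `n`; or all-`NA` with an
#'   `egsmodel_undefined_metric` warning for degenerate input.
#' @export
threshold_regression <- function(thresholds, t_avg) {
  keep <- !is.na(thresholds) & !is.na(t_avg)
  thresholds <- thresholds[keep]
  t_avg <- t_avg[keep]
  if (length(thresholds) < 3L || stats::var(t_avg) == 0) {
    undefined_metric("threshold regression needs >= 3 pixels with varying t_avg")
    return(list(intercept = NA_real_, slope = NA_real_, r = NA_real_,
                n = length(thresholds)))
  }
  fit <- lm(thresholds ~ t_avg)
  r <- if (stats::var(thresholds) == 0) 0 else cor(thresholds, t_avg)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       r = r, n = length(thresholds))
}

#' Annual area-mean end-of-season series
#'
#' Aggregates per-pixel-year dates into the per-year area mean for each
#' biome (and pooled over biomes), the series whose interannual variability
#' and trend are compared between models and observations.
#'
#' @param df Data frame with columns `year`, `biome` and the value column.
#' @param value Name of the day-of-year column to average (default
#'   `"egs_doy_observed"`). `NA` values (sentinels) are dropped.
#' @return Data frame with columns `biome` (including `"all"`), `year`,
#'   `mean_doy`, `n`.
#' @export
interannual_series <- function(df, value = "egs_doy_observed") {
  stopifnot(all(c("year", "biome", value) %in% names(df)))
  v <- df[[value]]
  keep <- !is.na(v)
  d <- data.frame(biome = df$biome[keep], year = df$year[keep],
                  doy = as.numeric(v[keep]))
  pooled <- d
  pooled$biome <- "all"
  d <- rbind(d, pooled)
  agg <- aggregate(doy ~ biome + year, data = d,
                   FUN = function(x) c(mean = mean(x), n = length(x)))
  out <- data.frame(biome = agg$biome, year = agg$year,
                    mean_doy = agg$doy[, "mean"],
                    n = as.integer(agg$doy[, "n"]))
  out[order(out$biome, out$year), ]
}

#' Linear trend of an annual series
#'
#' Ordinary least squares of annual mean end-of-season date on calendar
#' year, with a two-sided t-test of zero slope. A p-value is only reported
#' with at least 3 years.
#'
#' @param years Calendar years.
#' @param values Annual mean days-of-year.
#' @return List of class `trend_result`: `slope` (days/yr), `intercept`
#'   (DOY at year 0), `p_value` (`NA` when `n_years < 3`), `n_years`.
#' @export
trend_slope <- function(years, values) {
  keep <- !is.na(values) & !is.na(years)
  years <- years[keep]
  values <- values[keep]
  n <- length(years)
  if (n < 2L) stop("need at least 2 years for a trend", call. = FALSE)
  fit <- lm(values ~ years)
  p <- NA_real_
  if (n >= 3L && stats::var(values) > 0) {
    rss <- sum(fit$residuals^2)
    if (rss < 1e-10 * sum((values - mean(values))^2)) {
      p <- 0  # exact linear series
    } else {
      sm <- summary(fit)$coefficients
      if (nrow(sm) == 2L) p <- sm["years", "Pr(>|t|)"]
    }
  } else if (n >= 3L) {
    p <- 1  # flat series: slope exactly 0, no evidence against it
  }
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 p_value = p, n_years = n),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("trend: %+.3f days/yr over %d years (p = %s)\n", x$slope,
              x$n_years,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value)))
  invisible(x)
}

#' Per-biome and pooled validation report
#'
#' Computes the full validation suite for a set of predictions: both
#' definitions of R-squared, RMSE, mean absolute error, sentinel counts,
#' and the cumulative within-k-day curve, per biome and pooled.
#'
#' @param biome Biome label per pixel-year.
#' @param observed,predicted Days-of-year per pixel-year (`NA` in
#'   `predicted` marks a no-senescence sentinel).
#' @param k_max Largest tolerance for the cumulative curve (default 90).
#' @return A list of class `evaluation_report`: `metrics` (data frame,
#'   one row per biome plus `"all"`) and `curves` (named list of
#'   cumulative-curve data frames).
#' @export
evaluate_predictions <- function(biome, observed, predicted, k_max = 90L) {
  stopifnot(length(biome) == length(observed),
            length(observed) == length(predicted))
  groups <- c(list(all = seq_along(biome)),
              split(seq_along(biome), biome))
  rows <- list()
  curves <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    obs <- observed[idx]
    pred <- predicted[idx]
    n_sent <- sum(!is.na(obs) & is.na(pred))
    suppressWarnings({
      rows[[g]] <- data.frame(
        biome = g, n = sum(!is.na(obs)), n_sentinel = n_sent,
        r_squared = r_squared(obs, pred),
        r_squared_ss = r_squared(obs, pred, method = "ss"),
        rmse = rmse(obs, pred),
        mae = mean_absolute_error(obs, pred),
        within_10 = cumulative_within(obs, pred, 10),
        within_15 = cumulative_within(obs, pred, 15))
      curves[[g]] <- cumulative_curve(obs, pred, k_max)
    })
  }
  structure(list(metrics = do.call(rbind, rows), curves = curves),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat("validation of predicted end-of-season dates\n")
  print(x$metrics, digits = digits, row.names = FALSE)
  invisible(x)
}
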