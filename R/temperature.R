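#' Trailing running mean of a daily temperature series
#'
#' Smooths a daily series with a trailing window ending on the evaluated day:
#' the value at day-of-year `d` is the arithmetic mean of days
#' `d - window + 1, ..., d`. For the first `window - 1` days the window is
#' truncated to the available days `1..d`. A trailing (not centred) window is
#' used because senescence responds to the temperatures that precede a day,
#' and the truncated start is irrelevant to the July-onward threshold search.
#'
#' @param values Numeric vector, one value per day of year.
#' @param window Window length in days (default 10).
#' @return Numeric vector of the same length as `values`.
#' @examples
#' running_mean(1:20, 10)[20]  # mean(11:20) = 15.5
#' @export
running_mean <- function(values, window = 10L) {
  if (!is.numeric(window) || length(window) != 1L || !is.finite(window) ||
      window < 1) {
    stop("`window` must be a positive integer number of days", call. = FALSE)
  }
  window <- as.integer(window)
  if (!is.numeric(values) || length(values) == 0L) {
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  }
  n <- length(values)
  cs <- cumsum(values)
  d <- seq_len(n)
  lo <- pmax(d - window, 0L)
  (cs - c(0, cs)[lo + 1L]) / (d - lo)
}

#' Climatological summaries of a pixel's temperature record
#'
#' Computes the per-pixel climate quantities the phenology rules consume:
#' the mean annual temperature `t_avg` (all daily values pooled over the
#' supplied years) and the coldest calendar-month mean `t_coldest_month`
#' (minimum over the 12 months of the multi-year monthly means).
#'
#' `t_avg` is climatological (pooled over years) rather than per-year
#' because the threshold parameters are static over a study period;
#' see the package vignette for the per-year alternative.
#'
#' @param series_by_year Named list of daily temperature vectors, one per
#'   year; names are calendar years. Each vector has length 365 or 366
#'   matching the leap status of its year.
#' @return A list of class `pixel_climate` with elements `t_avg`,
#'   `t_coldest_month` and `n_years`.
#' @export
pixel_climate <- function(series_by_year) {
  if (!is.list(series_by_year) || length(series_by_year) == 0L) {
    stop("`series_by_year` must be a non-empty list of yearly series",
         call. = FALSE)
  }
  years <- names(series_by_year)
  if (is.null(years)) years <- rep(NA_character_, length(series_by_year))
  all_vals <- numeric(0)
  all_months <- integer(0)
  for (i in seq_along(series_by_year)) {
    v <- series_by_year[[i]]
    yr <- suppressWarnings(as.integer(years[[i]]))
    validate_series(v, if (is.na(yr)) NULL else yr)
    all_vals <- c(all_vals, v)
    all_months <- c(all_months, month_of_doy(length(v)))
  }
  monthly <- vapply(split(all_vals, all_months), mean, numeric(1))
  structure(
    list(t_avg = mean(all_vals),
         t_coldest_month = min(monthly),
         n_years = length(series_by_year)),
    class = "pixel_climate"
  )
}

#' @export
print.pixel_climate <- function(x, ...) {
  cat(sprintf("pixel climate over %d year(s): t_avg = %.2f degC, coldest month = %.2f degC\n",
              x$n_years, x$t_avg, x$t_coldest_month))
  invisible(x)
}
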