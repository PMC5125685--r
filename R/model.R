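#' Adaptive critical temperature threshold
#'
#' The critical 10-day running-mean temperature below which senescence is
#' triggered is a linear function of the local mean annual temperature:
#' `tcrit = a + b * t_avg`. The intercept `a` (degC) and slope `b`
#' (degC per degC) are biome-specific and estimated by calibration against
#' observed end-of-season dates; `t_avg` encodes the physiological
#' adaptation of plants to their local temperature environment.
#'
#' @param a Intercept in degC.
#' @param b Dimensionless slope (degC per degC of mean annual temperature).
#' @param t_avg Mean annual temperature in degC (vectorised).
#' @return Critical threshold(s) in degC.
#' @examples
#' tcrit(7, 0.02, 0)      # 7.0
#' tcrit(8, 0.272, -10)   # 5.28
#' @export
tcrit <- function(a, b, t_avg) {
  a + b * t_avg
}

# Internal: first index >= start at which `x` is below `threshold`
# (strictly, or non-strictly when inclusive). NA when no such day exists.
first_crossing <- function(x, threshold, start, inclusive = FALSE) {
  n <- length(x)
  if (!is.numeric(start) || length(start) != 1L || start < 1 || start > n) {
    stop("`search_start` must be a day-of-year within the series (1..", n,
         ")", call. = FALSE)
  }
  start <- as.integer(start)
  tail <- x[start:n]
  hit <- if (inclusive) tail <= threshold else tail < threshold
  i <- which(hit)
  if (length(i) == 0L) return(NA_integer_)
  start + i[[1L]] - 1L
}

#' Predict the end of the growing season with the adaptive-threshold model
#'
#' Senescence begins on the first day, at or after the midsummer search
#' start, on which the trailing `window`-day running-mean temperature falls
#' strictly below the critical threshold. When the running mean never drops
#' below the threshold before year end, `NA` is returned: an explicit
#' "no senescence detected" sentinel, never a fabricated date.
#'
#' The default `search_start` of day-of-year 183 fixes the "past July 1st"
#' gate at the same DOY in all years (July 2 in non-leap years); the one-day
#' leap shift is below the model's resolution.
#'
#' @param values Daily mean temperatures (degC) for one pixel-year,
#'   length 365 or 366.
#' @param threshold Critical temperature in degC (e.g. from [tcrit()]).
#' @param search_start First day-of-year eligible for senescence
#'   (default 183).
#' @param window Running-mean window in days (default 10).
#' @param fractional If `TRUE`, linearly interpolate the crossing between
#'   the bracketing days and return a fractional day-of-year. This yields
#'   a prediction continuous in the threshold, from which a smooth
#'   calibration objective can be built for gradient-based optimisers; the
#'   default integer dates are what calibration and evaluation use.
#' @return Integer day-of-year of predicted senescence onset (numeric when
#'   `fractional = TRUE`), or `NA` if the threshold is never crossed.
#' @seealso [predict_egs_ibis_tree()], [predict_egs_ibis_grass()]
#' @export
predict_egs_novel <- function(values, threshold, search_start = 183L,
                              window = 10L, fractional = FALSE) {
  sm <- running_mean(values, window)
  d <- first_crossing(sm, threshold, search_start, inclusive = FALSE)
  if (!fractional) return(d)
  if (is.na(d) || d == search_start) return(as.numeric(d))
  drop <- sm[d - 1L] - sm[d]
  if (drop <= 0) return(as.numeric(d))
  d - 1 + (sm[d - 1L] - threshold) / drop
}

#' Predict the end of the growing season with the IBIS tree rule
#'
#' The classical rule for trees in the IBIS dynamic vegetation model: leaf
#' fall is initiated when the 10-day running-mean temperature either falls
#' below 0 degC or falls to within 5 degC of the coldest monthly
#' temperature. The disjunction of the two triggers is equivalent to a
#' single threshold `max(0, t_coldest_month + 5)` degC; the running mean
#' must fall strictly below it. The same midsummer gate as the adaptive
#' model is applied so the two models are compared on equal terms.
#'
#' @inheritParams predict_egs_novel
#' @param t_coldest_month Coldest calendar-month mean temperature in degC
#'   (see [pixel_climate()]).
#' @return Integer day-of-year, or `NA_integer_` if never triggered.
#' @export
predict_egs_ibis_tree <- function(values, t_coldest_month,
                                  search_start = 183L, window = 10L) {
  sm <- running_mean(values, window)
  first_crossing(sm, max(0, t_coldest_month + 5), search_start,
                 inclusive = FALSE)
}

#' Predict the end of the growing season with the IBIS grass/shrub rule
#'
#' The classical IBIS rule for grasses and shrubs: leaf fall is initiated
#' when the 10-day running-mean temperature reaches 0 degC, read as
#' "less than or equal to" so a series sitting exactly at 0 degC triggers.
#'
#' @inheritParams predict_egs_novel
#' @return Integer day-of-year, or `NA_integer_` if never triggered.
#' @export
predict_egs_ibis_grass <- function(values, search_start = 183L,
                                   window = 10L) {
  sm <- running_mean(values, window)
  first_crossing(sm, 0, search_start, inclusive = TRUE)
}

#' Empirical temperature threshold at an observed senescence date
#'
#' The 10-day running-mean temperature on the observed end-of-season day:
#' the per-pixel empirical threshold whose relationship with mean annual
#' temperature motivates the adaptive model (and whose regression on
#' `t_avg` recovers the threshold parameters; see
#' [threshold_regression()]).
#'
#' @inheritParams predict_egs_novel
#' @param observed_egs Observed end-of-season day-of-year.
#' @return Temperature in degC.
#' @export
observed_threshold <- function(values, observed_egs, window = 10L) {
  sm <- running_mean(values, window)
  if (!is.numeric(observed_egs) || length(observed_egs) != 1L ||
      is.na(observed_egs) || observed_egs < 1 ||
      observed_egs > length(values)) {
    stop("`observed_egs` must be a valid day-of-year for this series",
         call. = FALSE)
  }
  sm[[as.integer(observed_egs)]]
}
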