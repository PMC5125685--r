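#' Known biome labels
#'
#' The IGBP-style vegetation classes the package recognises (evergreen
#' broadleaf forest, croplands and non-vegetated classes are outside the
#' model's scope).
#' @return Character vector.
#' @export
known_biomes <- function() {
  default_biome_params()$biome
}

#' Convert a long temperature table to a nested per-pixel store
#'
#' @param temperature Long data frame with columns `pixel_id`, `year`,
#'   `doy`, `tmean`, or an existing store (returned unchanged).
#' @return Named list: `store[[pixel_id]][[year]]` is that pixel-year's
#'   daily vector, ordered by day-of-year.
#' @export
temperature_store <- function(temperature) {
  if (is.list(temperature) && !is.data.frame(temperature)) {
    return(temperature)
  }
  need <- c("pixel_id", "year", "doy", "tmean")
  if (!all(need %in% names(temperature))) {
    stop("temperature table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  lapply(split(temperature, temperature$pixel_id), function(d) {
    lapply(split(d, d$year), function(dy) {
      dy <- dy[order(dy$doy), ]
      if (!identical(as.integer(dy$doy), seq_len(nrow(dy)))) {
        stop("pixel '", dy$pixel_id[[1]], "' year ", dy$year[[1]],
             " has missing or duplicated days", call. = FALSE)
      }
      dy$tmean
    })
  })
}

#' Read a pixel table from CSV
#'
#' Schema: `pixel_id, lat, lon, biome, t_avg, year, egs_doy_observed`
#' (one row per pixel-year; `lat`, `lon`, `t_avg` optional). Validation is
#' strict — unknown biome labels and out-of-range dates are errors naming
#' the offending value and row, never silent `NA`s.
#'
#' @param path CSV file path.
#' @param biomes Accepted biome labels (default [known_biomes()]).
#' @return Data frame.
#' @export
read_pixel_table <- function(path, biomes = known_biomes()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("pixel_id", "biome", "year", "egs_doy_observed")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$biome %in% biomes)
  if (length(bad)) {
    stop(path, ", row ", bad[[1]], ": unknown biome label '",
         df$biome[[bad[[1]]]], "'", call. = FALSE)
  }
  egs <- df$egs_doy_observed
  bad <- which(!is.na(egs) & (!is.finite(egs) | egs < 1 | egs > 366 |
                                egs != round(egs)))
  if (length(bad)) {
    stop(path, ", row ", bad[[1]], ": egs_doy_observed = ",
         egs[[bad[[1]]]], " is not a day-of-year in [1, 366]",
         call. = FALSE)
  }
  bad <- which(is.na(df$year) | df$year != round(df$year))
  if (length(bad)) {
    stop(path, ", row ", bad[[1]], ": invalid year", call. = FALSE)
  }
  df
}

#' Write a pixel table to CSV
#' @param pixels Data frame as in [read_pixel_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pixel_table <- function(pixels, path) {
  write.csv(pixels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format daily temperature table from CSV
#'
#' Schema: `pixel_id, year, doy, tmean`. Each pixel-year must be complete
#' (every day present exactly once, length matching the leap status) and
#' within the plausible physical range; violations are errors naming the
#' pixel and value, never silent coercion.
#'
#' @param path CSV file path.
#' @return Long data frame.
#' @export
read_temperature <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("pixel_id", "year", "doy", "tmean")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df$tmean) || any(!is.finite(df$tmean))) {
    stop(path, ": non-finite temperature values", call. = FALSE)
  }
  bad <- which(df$tmean < -90 | df$tmean > 60)
  if (length(bad)) {
    stop(path, ", row ", bad[[1]], ": tmean = ", df$tmean[[bad[[1]]]],
         " degC outside the plausible [-90, 60] range", call. = FALSE)
  }
  bad <- which(is.na(df$doy) | df$doy < 1 | df$doy > 366)
  if (length(bad)) {
    stop(path, ", row ", bad[[1]], ": doy out of [1, 366]", call. = FALSE)
  }
  # completeness per pixel-year is enforced on conversion
  invisible(temperature_store(df))
  df
}

#' Write a long-format temperature table to CSV
#' @param temperature Long data frame (`pixel_id`, `year`, `doy`, `tmean`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_temperature <- function(temperature, path) {
  write.csv(temperature, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check that every pixel-year has a complete temperature record
#'
#' @param pixels Pixel table.
#' @param temperature Long table or store.
#' @return `TRUE` invisibly; referential violations are errors.
#' @export
check_referential <- function(pixels, temperature) {
  store <- temperature_store(temperature)
  for (i in seq_len(nrow(pixels))) {
    pid <- pixels$pixel_id[[i]]
    yr <- pixels$year[[i]]
    series <- store[[pid]][[as.character(yr)]]
    if (is.null(series)) {
      stop("pixel '", pid, "' year ", yr,
           " referenced by the pixel table has no temperature record",
           call. = FALSE)
    }
    validate_series(series, yr,
                    what = sprintf("temperature for pixel '%s' year %s",
                                   pid, yr))
  }
  invisible(TRUE)
}

#' Write/read ground-truth parameters as JSON
#'
#' @param truth List with `params_by_biome` (data frame `biome`, `a`, `b`)
#'   and optionally a config echo.
#' @param path JSON file path.
#' @return `path` invisibly (write); the truth list (read).
#' @export
write_truth <- function(truth, path) {
  out <- truth
  if (!is.null(out$config)) out$config <- unclass(out$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x
}

#' Write a per-biome parameter table to CSV
#'
#' The conventional calibrated-parameter table (biome, a, b) with
#' provenance columns.
#' @param results A `calibration_set` from [calibrate_all()], or a data
#'   frame already in table form.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_params_csv <- function(results, path) {
  tab <- if (is.data.frame(results)) results else params_table(results)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-biome parameter table from CSV
#' @param path CSV with at least columns `biome`, `a`, `b`.
#' @return Data frame.
#' @export
read_params_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("biome", "a", "b") %in% names(df))) {
    stop(path, ": parameter table needs columns biome, a, b",
         call. = FALSE)
  }
  df
}
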