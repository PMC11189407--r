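# Climatological characterization: monthly/annual summaries, decadal trend
# with t-test, and the 11-class percentile thermal classification.

#' Ordered labels of the 11 percentile thermal classes
#'
#' Band index 1 is the coldest (below the 5th percentile), 6 is "normal"
#' (40th-60th percentile), 11 the warmest (above the 95th). Labels are
#' cosmetic metadata over the band indices.
#' @return Character vector of length 11.
#' @export
thermal_class_labels <- function() {
  c("extremely cold", "anomalously cold", "very cold", "cold",
    "slightly cold", "normal", "light warm", "warm", "very warm",
    "anomalously warm", "extremely warm")
}

#' Monthly and annual climatology of a temperature series
#'
#' @param temps Temperature series tibble (`year`, `month`, `temp_c`).
#' @return A list of class `"ssr_climatology"` with elements
#'   `monthly` (tibble: month, mean, sd, n_years),
#'   `annual` (tibble: year, temp_annual; complete years only), and
#'   `overall` (one-row tibble: mean and sd of the annual means, n_years).
#'   Incomplete years are excluded from the annual series with a warning.
#' @export
climatology_summary <- function(temps) {
  temps <- validate_temperature_series(temps)
  monthly <- temps |>
    dplyr::summarise(mean = mean(.data$temp_c),
                     sd = stats::sd(.data$temp_c),
                     n_years = dplyr::n(), .by = "month") |>
    dplyr::arrange(.data$month)
  annual <- complete_annual_means(temps)
  n_all <- dplyr::n_distinct(temps$year)
  if (nrow(annual) == 0L)
    stop_ssr("no complete calendar year in the temperature series")
  if (nrow(annual) < n_all)
    warning(n_all - nrow(annual),
            " incomplete year(s) excluded from the annual series",
            call. = FALSE)
  overall <- tibble::tibble(mean = mean(annual$temp_annual),
                            sd = stats::sd(annual$temp_annual),
                            n_years = nrow(annual))
  structure(list(monthly = monthly, annual = annual, overall = overall),
            class = "ssr_climatology")
}

#' @export
print.ssr_climatology <- function(x, ...) {
  cat(sprintf("Climatology over %d complete years: annual mean %.2f degC (sd %.2f)\n",
              x$overall$n_years, x$overall$mean, x$overall$sd))
  cat(sprintf("Monthly means %.1f..%.1f degC\n",
              min(x$monthly$mean), max(x$monthly$mean)))
  invisible(x)
}

#' Linear trend of an annual series with a t-test on the slope
#'
#' Ordinary least-squares regression of the annual value on calendar year;
#' the slope is reported per decade with its two-sided t-test.
#'
#' @param annual Tibble with columns `year` and a value column (default
#'   `temp_annual`), e.g. `climatology_summary(temps)$annual`.
#' @param value Name of the value column.
#' @param alpha Significance level for the flag (default 0.05).
#' @return One-row tibble: `slope_per_decade`, `t_statistic`, `p_value`,
#'   `significant`.
#' @export
linear_trend <- function(annual, value = "temp_annual", alpha = 0.05) {
  if (nrow(annual) < 3L) stop_ssr("need at least 3 years for a trend")
  fit <- stats::lm(annual[[value]] ~ annual$year)
  sm <- summary(fit)$coefficients
  tibble::tibble(
    slope_per_decade = unname(sm[2, 1]) * 10,
    t_statistic = unname(sm[2, 3]),
    p_value = unname(sm[2, 4]),
    significant = unname(sm[2, 4]) < alpha
  )
}

#' Percentile thresholds of a reference sample
#'
#' Quantiles by linear interpolation between order statistics (the default
#' estimator of mainstream statistical environments).
#'
#' @param values Numeric vector, length >= 2.
#' @param probs Percentile levels in percent, strictly increasing within
#'   (0, 100). Default: the 5, 10, 20, 30, 40, 60, 70, 80, 90, 95 thresholds
#'   that delimit the 11 thermal classes.
#' @return Named numeric vector of thresholds (non-decreasing).
#' @export
percentile_thresholds <- function(values,
                                  probs = c(5, 10, 20, 30, 40, 60, 70, 80, 90, 95)) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop_ssr("need at least 2 values")
  if (any(probs <= 0 | probs >= 100) || any(diff(probs) <= 0))
    stop_ssr("`probs` must be strictly increasing within (0, 100)")
  stats::quantile(values, probs = probs / 100, type = 7, names = TRUE)
}

# Band index 1..(K+1) from K thresholds; upper-closed intervals (a value equal
# to a threshold joins the lower band); with tied thresholds the middle of the
# tied span is taken, so an all-equal reference degenerates to the middle band.
band_index <- function(values, thresholds) {
  vapply(values, function(v) {
    lo <- 1L + sum(thresholds < v)
    hi <- 1L + sum(thresholds <= v)
    as.integer(floor((lo + hi) / 2))
  }, integer(1))
}

#' Percentile thermal classification of a temperature series
#'
#' Classifies each year's annual mean and each month's value into one of 11
#' ordered classes delimited by the 5th-95th percentile thresholds of the
#' reference period, computed separately for the annual scope and for each
#' calendar month.
#'
#' @param temps Temperature series tibble (`year`, `month`, `temp_c`).
#' @param reference_period Length-2 integer vector (first, last year) over
#'   which thresholds are computed; default the full span of `temps`.
#' @param probs Percentile levels in percent (default 5..95 as in
#'   [percentile_thresholds()]).
#' @return A tibble of class `"ssr_thermal"` with columns `scope`
#'   (`"annual"` or `"month_1"`..`"month_12"`), `year`, `value` (degC),
#'   `class` (band index 1..11) and `label`. The per-scope threshold tables
#'   are attached as attribute `"thresholds"`.
#' @export
classify_thermal <- function(temps, reference_period = NULL,
                             probs = c(5, 10, 20, 30, 40, 60, 70, 80, 90, 95)) {
  temps <- validate_temperature_series(temps)
  if (is.null(reference_period))
    reference_period <- range(temps$year)
  ref <- function(df) df[df$year >= reference_period[1] &
                           df$year <= reference_period[2], ]
  labels <- thermal_class_labels()
  pieces <- list()
  thresholds <- list()
  ann <- complete_annual_means(temps)
  thr <- percentile_thresholds(ref(ann)$temp_annual, probs)
  thresholds[["annual"]] <- thr
  pieces[["annual"]] <- tibble::tibble(
    scope = "annual", year = ann$year, value = ann$temp_annual,
    class = band_index(ann$temp_annual, thr))
  for (m in 1:12) {
    sub <- temps[temps$month == m, ]
    scope <- paste0("month_", m)
    thr <- percentile_thresholds(ref(sub)$temp_c, probs)
    thresholds[[scope]] <- thr
    pieces[[scope]] <- tibble::tibble(
      scope = scope, year = sub$year, value = sub$temp_c,
      class = band_index(sub$temp_c, thr))
  }
  out <- dplyr::bind_rows(pieces)
  out$label <- factor(labels[out$class], levels = labels, ordered = TRUE)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("ssr_thermal", class(out))
  out
}

#' Export a thermal classification as a heat-map table
#'
#' Wide layout: one row per scope (annual + 12 months), one column per year,
#' cells holding the band index 1..11.
#'
#' @param classification Result of [classify_thermal()].
#' @param path Optional file path; when given, the table is written as CSV.
#' @return The wide tibble (invisibly when `path` is given).
#' @export
thermal_class_table <- function(classification, path = NULL) {
  wide <- classification |>
    tibble::as_tibble() |>
    dplyr::select("scope", "year", "class") |>
    tidyr::pivot_wider(names_from = "year", values_from = "class") |>
    dplyr::arrange(match(.data$scope, c("annual", paste0("month_", 1:12))))
  if (!is.null(path)) {
    readr::write_csv(wide, path, progress = FALSE)
    return(invisible(wide))
  }
  wide
}
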