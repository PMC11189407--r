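# Synthetic temperature and birth-count generators with known ground truth.
#
# The generators emulate the two data streams of the historical Poznań study
# design: a homogenized monthly mean air-temperature series for a mid-European
# station, and monthly counts of live births by sex whose girl probability
# follows a configurable trend + season + distributed-lag-of-temperature
# structure on the logit scale.

#' Station climatology for the temperature simulator
#'
#' Defaults describe a Poznań-like mid-European climate over 1848--1900:
#' annual mean 7.5 degC, January mean -3.0 degC, July mean 18.1 degC, monthly
#' standard deviations from 1.2 degC (August) to 3.0 degC (January/February),
#' and a weak warming trend of 0.1 degC per decade.
#'
#' @param monthly_means Numeric length 12, mean temperature (degC) per
#'   calendar month.
#' @param monthly_sds Numeric length 12, between-year standard deviation
#'   (degC) per calendar month; all `>= 0`.
#' @param trend_per_decade Linear warming trend, degC per 10 years.
#' @param start_year,end_year First and last simulated calendar year.
#' @return An object of class `"clim_profile"`.
#' @export
#' @examples
#' climatology_profile()
climatology_profile <- function(monthly_means = c(-3.0, -1.6, 1.4, 6.8, 12.8, 16.5,
                                                  18.1, 17.3, 12.9, 7.6, 2.8, -1.6),
                                monthly_sds = c(3.0, 3.0, 2.2, 1.6, 1.5, 1.4,
                                                1.3, 1.2, 1.4, 1.6, 2.0, 2.6),
                                trend_per_decade = 0.1,
                                start_year = 1848L, end_year = 1900L) {
  if (length(monthly_means) != 12L || length(monthly_sds) != 12L)
    stop_ssr("`monthly_means` and `monthly_sds` must each have 12 values")
  if (any(!is.finite(monthly_means)) || any(!is.finite(monthly_sds)))
    stop_ssr("climatology values must be finite")
  if (any(monthly_sds < 0)) stop_ssr("`monthly_sds` must be non-negative")
  if (end_year < start_year)
    stop_ssr("`end_year` must not precede `start_year`")
  structure(
    list(monthly_means = as.numeric(monthly_means),
         monthly_sds = as.numeric(monthly_sds),
         trend_per_decade = as.numeric(trend_per_decade),
         start_year = as.integer(start_year),
         end_year = as.integer(end_year)),
    class = "clim_profile"
  )
}

#' Simulate a monthly mean temperature series
#'
#' Each monthly value is the climatological mean for that calendar month, plus
#' a linear trend contribution `trend_per_decade * (year - start_year) / 10`,
#' plus zero-mean noise with the month's standard deviation. Noise is
#' independent between months by default; `ar1` adds first-order
#' autocorrelation to the standardised anomalies.
#'
#' @param profile A [climatology_profile()].
#' @param seed Integer seed; identical seeds give identical series.
#' @param ar1 AR(1) coefficient for the standardised monthly anomalies, in
#'   `(-1, 1)`. Default 0 (independent noise).
#' @return A tibble with columns `year`, `month`, `temp_c`, one row per
#'   (year, month) in the profile's range, in chronological order.
#' @export
#' @examples
#' temps <- simulate_temperature(climatology_profile(), seed = 1)
simulate_temperature <- function(profile, seed, ar1 = 0) {
  stopifnot(inherits(profile, "clim_profile"))
  if (abs(ar1) >= 1) stop_ssr("`ar1` must lie in (-1, 1)")
  years <- seq(profile$start_year, profile$end_year)
  grid <- tibble::tibble(
    year = rep(years, each = 12L),
    month = rep(1:12, times = length(years))
  )
  n <- nrow(grid)
  z <- with_seed(seed, stats::rnorm(n))
  if (ar1 != 0) {
    e <- numeric(n)
    e[1] <- z[1]
    for (t in 2:n) e[t] <- ar1 * e[t - 1] + sqrt(1 - ar1^2) * z[t]
    z <- e
  }
  grid$temp_c <- profile$monthly_means[grid$month] +
    profile$trend_per_decade * (grid$year - profile$start_year) / 10 +
    profile$monthly_sds[grid$month] * z
  grid
}

#' Default ground-truth lag profile
#'
#' A smooth single-trough cubic in the lag index, scaled to match the order of
#' magnitude seen in monthly-temperature distributed-lag analyses of the sex
#' ratio (a few thousandths of a logit per degC): clearly negative around lags
#' -6..-3 (the months just before conception), mildly negative through early
#' pregnancy, and slightly positive at the +9 edge. Being an exact cubic, it
#' lies in the span of a degree-3 polynomial lag constraint.
#'
#' @param scale Multiplier applied to the profile (default 1).
#' @return Named numeric vector of length 19 (names `"-9"` ... `"9"`).
#' @export
default_lag_profile <- function(scale = 1) {
  u <- (LAGS + 9) / 18
  val <- 0.001 - 0.05 * u + 0.12 * u^2 - 0.064 * u^3
  stats::setNames(scale * val, as.character(LAGS))
}

#' Ground-truth scenario for the birth-count simulator
#'
#' Houses the generative analogues of the distributed-lag additive model's
#' terms: a logit-scale baseline, an annual trend shape, a 12-value seasonal
#' shape indexed by birth month, and a 19-value temperature lag profile
#' (lags -9..+9 around conception).
#'
#' @param lag_profile Numeric length 19, logit-scale effect per degC for lags
#'   -9..+9 in order. Default [default_lag_profile()].
#' @param trend_shape Function of calendar birth year returning a logit-scale
#'   contribution. Default: constant 0.
#' @param season_shape Numeric length 12, logit-scale contribution per birth
#'   month. Default: all 0.
#' @param baseline_logit Baseline log-odds of a girl birth. The default
#'   -0.0556 is the logit of a girl proportion of about 0.4861, the level
#'   typical of historical European birth registers.
#' @param births_per_month Positive integer (scalar) number of births per
#'   simulated month. Default 104, the study-scale monthly count.
#' @param seed Integer seed used by [simulate_birth_series()].
#' @return An object of class `"ssr_scenario"`.
#' @export
scenario_config <- function(lag_profile = default_lag_profile(),
                            trend_shape = function(year) rep(0, length(year)),
                            season_shape = rep(0, 12),
                            baseline_logit = -0.0556,
                            births_per_month = 104L,
                            seed = 1L) {
  if (length(lag_profile) != 19L)
    stop_ssr("`lag_profile` must have exactly 19 entries (lags -9..+9)")
  if (length(season_shape) != 12L)
    stop_ssr("`season_shape` must have 12 entries")
  if (!is.function(trend_shape)) stop_ssr("`trend_shape` must be a function")
  if (births_per_month < 1) stop_ssr("`births_per_month` must be >= 1")
  structure(
    list(lag_profile = as.numeric(lag_profile),
         trend_shape = trend_shape,
         season_shape = as.numeric(season_shape),
         baseline_logit = as.numeric(baseline_logit),
         births_per_month = as.integer(births_per_month),
         seed = as.integer(seed)),
    class = "ssr_scenario"
  )
}

#' Ground-truth linear predictor for a model-frame row
#'
#' Returns `baseline + trend_shape(birth_year) + season_shape[birth_month] +
#' sum over lags of lag_profile * lag temperature`, the logit of the true girl
#' probability under the scenario. Deterministic.
#'
#' @param scenario A [scenario_config()].
#' @param frame Data frame with columns `birth_year`, `birth_month` and the 19
#'   lag columns [lag_col_names()]; one value is returned per row.
#' @return Numeric vector of logits, one per row of `frame`.
#' @export
true_linear_predictor <- function(scenario, frame) {
  stopifnot(inherits(scenario, "ssr_scenario"))
  cols <- lag_col_names()
  missing_cols <- setdiff(c("birth_year", "birth_month", cols), names(frame))
  if (length(missing_cols) > 0)
    stop_ssr("frame is missing columns: ", paste(missing_cols, collapse = ", "))
  lag_mat <- as.matrix(frame[cols])
  if (anyNA(lag_mat)) stop_ssr("frame has missing lag temperatures")
  as.numeric(
    scenario$baseline_logit +
      scenario$trend_shape(frame$birth_year) +
      scenario$season_shape[frame$birth_month] +
      lag_mat %*% scenario$lag_profile
  )
}

#' Simulate monthly birth counts by sex
#'
#' For every birth month whose full conception lag window (and conception
#' calendar year, when within the series) is covered by `temps`, draws
#' `girls ~ Binomial(births_per_month, plogis(true linear predictor))` and
#' sets `boys = births_per_month - girls`. Seeded by `scenario$seed`.
#'
#' @param temps Temperature series tibble (`year`, `month`, `temp_c`).
#' @param scenario A [scenario_config()].
#' @param years Optional integer vector of birth years to simulate. When
#'   given, a missing required temperature raises an error naming the first
#'   missing (year, month); when `NULL` (default) the simulated range is every
#'   birth month with complete lag coverage.
#' @return A tibble `year`, `month`, `boys`, `girls`, in chronological order.
#' @export
#' @examples
#' temps <- simulate_temperature(climatology_profile(), seed = 1)
#' births <- simulate_birth_series(temps, scenario_config(seed = 2))
simulate_birth_series <- function(temps, scenario, years = NULL) {
  stopifnot(inherits(scenario, "ssr_scenario"))
  temps <- validate_temperature_series(temps)
  if (is.null(years)) {
    cand <- dplyr::distinct(temps, .data$year, .data$month)
  } else {
    cand <- tibble::tibble(year = rep(as.integer(years), each = 12L),
                           month = rep(1:12, length(years)))
  }
  cov <- lag_covariates(cand$year, cand$month, temps)
  keep <- stats::complete.cases(cov[lag_col_names()])
  if (!is.null(years) && any(!keep)) {
    bad <- cov[!keep, ]
    miss <- first_missing_lag(bad, temps)
    stop_ssr(sprintf(
      "temperature series does not cover the lag window: missing (%d, %d)",
      miss$year, miss$month))
  }
  if (!any(keep))
    stop_ssr("temperature series covers no complete lag window")
  sim <- cov[keep, ]
  eta <- true_linear_predictor(scenario, sim)
  p <- stats::plogis(eta)
  m <- scenario$births_per_month
  girls <- with_seed(scenario$seed, stats::rbinom(nrow(sim), m, p))
  tibble::tibble(year = sim$birth_year, month = sim$birth_month,
                 boys = m - girls, girls = girls)
}

# First (year, month) needed by a row's lag window but absent from temps.
first_missing_lag <- function(rows, temps) {
  key <- temps$year * 12L + temps$month
  for (i in seq_len(nrow(rows))) {
    for (k in LAGS) {
      s <- month_shift(rows$conception_year[i], rows$conception_month[i], k)
      if (!((s$year * 12L + s$month) %in% key))
        return(list(year = s$year, month = s$month))
    }
  }
  stop_ssr("no missing lag month found")
}
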