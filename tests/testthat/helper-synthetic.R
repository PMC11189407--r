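# Shared fixtures, built in code: small climate profiles, synthetic frames,
# and an independent month-walking oracle for lag checks.

small_profile <- function(start_year = 1848, end_year = 1866) {
  climatology_profile(start_year = start_year, end_year = end_year)
}

# Simulate temps + births and assemble the model frame (~200 rows by default).
make_frame <- function(seed, scenario = NULL, start_year = 1848,
                       end_year = 1866) {
  temps <- simulate_temperature(small_profile(start_year, end_year),
                                seed = seed)
  scenario <- scenario %||% scenario_config(seed = seed + 1L)
  births <- simulate_birth_series(temps, scenario)
  suppressMessages(assemble_model_frame(births, temps))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent month arithmetic: step one month at a time.
walk_month <- function(year, month, k) {
  step <- if (k >= 0) 1L else -1L
  for (i in seq_len(abs(k))) {
    month <- month + step
    if (month == 13L) { month <- 1L; year <- year + 1L }
    if (month == 0L) { month <- 12L; year <- year - 1L }
  }
  c(year = year, month = month)
}

temp_lookup <- function(temps, year, month) {
  v <- temps$temp_c[temps$year == year & temps$month == month]
  if (length(v) == 0) NA_real_ else v
}
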