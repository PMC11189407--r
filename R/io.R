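# Reading/writing the aggregated birth and temperature tables, conception-date
# estimation, and assembly of the lagged-temperature model frame.

validate_birth_series <- function(df, source = "birth series") {
  need <- c("year", "month", "boys", "girls")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop_ssr(source, ": missing columns ", paste(missing_cols, collapse = ", "))
  df <- tibble::as_tibble(df)[need]
  bad <- which(df$month < 1 | df$month > 12 | df$month != round(df$month))
  if (length(bad) > 0)
    stop_ssr(source, ": month outside 1-12 in row ", bad[1])
  bad <- which(df$boys < 0 | df$girls < 0)
  if (length(bad) > 0)
    stop_ssr(source, ": negative count in row ", bad[1])
  key <- paste(df$year, df$month)
  if (anyDuplicated(key) > 0)
    stop_ssr(source, ": duplicate (year, month) in row ", anyDuplicated(key))
  for (col in need) df[[col]] <- as.integer(df[[col]])
  dplyr::arrange(df, .data$year, .data$month)
}

validate_temperature_series <- function(df, source = "temperature series") {
  need <- c("year", "month", "temp_c")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop_ssr(source, ": missing columns ", paste(missing_cols, collapse = ", "))
  df <- tibble::as_tibble(df)[need]
  bad <- which(df$month < 1 | df$month > 12 | df$month != round(df$month))
  if (length(bad) > 0)
    stop_ssr(source, ": month outside 1-12 in row ", bad[1])
  if (any(!is.finite(df$temp_c)))
    stop_ssr(source, ": non-finite temperature in row ",
             which(!is.finite(df$temp_c))[1])
  key <- paste(df$year, df$month)
  if (anyDuplicated(key) > 0)
    stop_ssr(source, ": duplicate (year, month) in row ", anyDuplicated(key))
  df$year <- as.integer(df$year)
  df$month <- as.integer(df$month)
  df$temp_c <- as.numeric(df$temp_c)
  dplyr::arrange(df, .data$year, .data$month)
}

read_delim_sniff <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Read an aggregated monthly birth table
#'
#' Expects a delimited text file (comma, semicolon or tab) with one row per
#' (year, month) and columns for year, month and the two sex-specific birth
#' counts. `col_map` adapts external layouts -- e.g. the deposited Poznań
#' register table -- by naming which input columns hold each field.
#'
#' @param path Path to a delimited text file with a header row.
#' @param col_map Named character vector mapping the canonical names
#'   `year`, `month`, `boys`, `girls` to the file's column names. Matching is
#'   case-insensitive; common synonyms (`males`/`females`, `m`/`f`) are tried
#'   automatically when a mapped name is absent.
#' @return A validated tibble (`year`, `month`, `boys`, `girls`), sorted by
#'   (year, month).
#' @export
read_birth_table <- function(path,
                             col_map = c(year = "year", month = "month",
                                         boys = "boys", girls = "girls")) {
  raw <- read_delim_sniff(path)
  synonyms <- list(
    year = c("year", "yr", "birth_year"),
    month = c("month", "mon", "birth_month"),
    boys = c("boys", "males", "male", "m", "n_boys"),
    girls = c("girls", "females", "female", "f", "n_girls")
  )
  out <- list()
  lowered <- tolower(names(raw))
  for (field in c("year", "month", "boys", "girls")) {
    cands <- unique(c(tolower(col_map[[field]]), synonyms[[field]]))
    hit <- match(cands, lowered)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0)
      stop_ssr("cannot find a column for '", field, "' in ", path)
    out[[field]] <- raw[[hit[1]]]
  }
  validate_birth_series(tibble::as_tibble(out), source = path)
}

#' Read a monthly mean temperature table
#'
#' Accepts either long format (columns year, month, temperature) or wide
#' format (a year column plus 12 monthly columns named by number, month name
#' or abbreviation).
#'
#' @param path Path to a delimited text file with a header row.
#' @return A validated tibble (`year`, `month`, `temp_c`), sorted.
#' @export
read_temperature_table <- function(path) {
  raw <- read_delim_sniff(path)
  lowered <- tolower(names(raw))
  temp_names <- c("temp_c", "temp", "temperature", "t", "tavg", "mean_temp")
  year_idx <- match(c("year", "yr"), lowered)
  year_idx <- year_idx[!is.na(year_idx)][1]
  if (is.na(year_idx)) stop_ssr("cannot find a 'year' column in ", path)
  temp_idx <- match(temp_names, lowered)
  temp_idx <- temp_idx[!is.na(temp_idx)][1]
  if (!is.na(temp_idx)) {
    month_idx <- match(c("month", "mon"), lowered)
    month_idx <- month_idx[!is.na(month_idx)][1]
    if (is.na(month_idx)) stop_ssr("cannot find a 'month' column in ", path)
    long <- tibble::tibble(year = raw[[year_idx]], month = raw[[month_idx]],
                           temp_c = raw[[temp_idx]])
    return(validate_temperature_series(long, source = path))
  }
  # wide: find the 12 month columns
  mon_keys <- list(as.character(1:12), sprintf("m%d", 1:12),
                   tolower(month.abb), tolower(month.name))
  for (keys in mon_keys) {
    idx <- match(keys, lowered)
    if (all(!is.na(idx))) {
      long <- tidyr::pivot_longer(
        raw[c(year_idx, idx)],
        cols = -1, names_to = "month_name", values_to = "temp_c")
      long$month <- match(tolower(long$month_name), keys)
      long <- tibble::tibble(year = long[[1]], month = long$month,
                             temp_c = long$temp_c)
      return(validate_temperature_series(long, source = path))
    }
  }
  stop_ssr("cannot interpret ", path,
           " as long (year, month, temp) or wide (year x 12 months)")
}

#' Write birth / temperature tables
#'
#' Plain comma-separated text, readable back by the corresponding reader
#' (write-then-read is the identity).
#'
#' @param df A birth series (`year`, `month`, `boys`, `girls`) or temperature
#'   series (`year`, `month`, `temp_c`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_birth_table <- function(df, path) {
  readr::write_csv(validate_birth_series(df), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_birth_table
#' @export
write_temperature_table <- function(df, path) {
  readr::write_csv(validate_temperature_series(df), path, progress = FALSE)
  invisible(path)
}

#' Estimate the conception date from a birth month
#'
#' The conception date is taken as the 15th day of the birth month minus 280
#' days (40 weeks, the conventional human gestation length), using true
#' calendar arithmetic (leap-aware, proleptic Gregorian). The conception month
#' is the calendar month containing that date.
#'
#' @param birth_year,birth_month Integer vectors (recycled to equal length);
#'   months in 1..12.
#' @return A tibble with columns `birth_year`, `birth_month`,
#'   `assumed_birth_day` (always 15), `conception_date` (a `Date`),
#'   `conception_year`, `conception_month`.
#' @export
#' @examples
#' estimate_conception(1870, 10)  # conception 1870-01-08
estimate_conception <- function(birth_year, birth_month) {
  n <- max(length(birth_year), length(birth_month))
  birth_year <- rep_len(as.integer(birth_year), n)
  birth_month <- rep_len(as.integer(birth_month), n)
  if (any(birth_month < 1 | birth_month > 12))
    stop_ssr("`birth_month` must be in 1..12")
  birth_date <- as.Date(sprintf("%04d-%02d-15", birth_year, birth_month))
  conception <- birth_date - 280L
  lt <- as.POSIXlt(conception)
  tibble::tibble(
    birth_year = birth_year, birth_month = birth_month,
    assumed_birth_day = 15L,
    conception_date = conception,
    conception_year = lt$year + 1900L,
    conception_month = lt$mon + 1L
  )
}

#' Annual mean temperature of one or more calendar years
#'
#' Arithmetic mean of the 12 monthly values; a year with any missing month
#' raises a coverage error.
#'
#' @param temps Temperature series tibble (`year`, `month`, `temp_c`).
#' @param year Integer vector of calendar years.
#' @return Numeric vector of annual means, one per requested year.
#' @export
annual_mean_temperature <- function(temps, year) {
  temps <- validate_temperature_series(temps)
  vapply(as.integer(year), function(y) {
    sub <- temps[temps$year == y, ]
    if (nrow(sub) != 12L)
      stop_ssr("temperature record for year ", y, " is incomplete (",
               nrow(sub), " of 12 months)")
    mean(sub$temp_c)
  }, numeric(1))
}

# Annual means of every complete year, silently skipping incomplete ones.
complete_annual_means <- function(temps) {
  temps |>
    dplyr::summarise(n = dplyr::n(), temp_annual = mean(.data$temp_c),
                     .by = "year") |>
    dplyr::filter(.data$n == 12L) |>
    dplyr::select("year", "temp_annual") |>
    dplyr::arrange(.data$year)
}

# Conception estimate + 19 lag temperature columns for given birth months.
# Missing temperatures are left NA (filtering is the caller's decision).
lag_covariates <- function(birth_year, birth_month, temps) {
  con <- estimate_conception(birth_year, birth_month)
  lookup <- stats::setNames(temps$temp_c, temps$year * 12L + temps$month)
  out <- con[c("birth_year", "birth_month", "conception_year",
               "conception_month")]
  for (k in LAGS) {
    s <- month_shift(con$conception_year, con$conception_month, k)
    out[[lag_col_names(k)]] <- unname(lookup[as.character(s$year * 12L + s$month)])
  }
  out
}

#' Assemble the model frame of birth counts and lagged temperatures
#'
#' One row per birth month: sex-specific counts, the estimated conception
#' month, the annual mean temperature of the configured calendar year, and
#' the 19 monthly temperatures at lags -9..+9 around the conception month
#' (lag 0 = conception month; lag +9 = the birth month itself). Rows whose lag
#' window or annual-mean year is not fully covered by the temperature record
#' are dropped listwise, with a message reporting the count; the dropped
#' (year, month) pairs are attached as attribute `"dropped"`.
#'
#' @param births Birth series tibble (`year`, `month`, `boys`, `girls`).
#' @param temps Temperature series tibble (`year`, `month`, `temp_c`).
#' @param annual_year Which calendar year's annual mean enters the frame as
#'   `temp_year_mean`: `"conception"` (default) or `"birth"`.
#' @return A tibble with columns `birth_year`, `birth_month`, `boys`, `girls`,
#'   `total`, `conception_year`, `conception_month`, `temp_year_mean`, and
#'   `lag_m9` ... `lag_p9`.
#' @export
assemble_model_frame <- function(births, temps,
                                 annual_year = c("conception", "birth")) {
  annual_year <- match.arg(annual_year)
  births <- validate_birth_series(births)
  temps <- validate_temperature_series(temps)
  cov <- lag_covariates(births$year, births$month, temps)
  ann <- complete_annual_means(temps)
  ann_year <- if (annual_year == "conception") cov$conception_year else births$year
  frame <- dplyr::bind_cols(
    cov[c("birth_year", "birth_month")],
    tibble::tibble(boys = births$boys, girls = births$girls,
                   total = births$boys + births$girls),
    cov[c("conception_year", "conception_month")],
    tibble::tibble(temp_year_mean = ann$temp_annual[match(ann_year, ann$year)]),
    cov[lag_col_names()]
  )
  complete <- stats::complete.cases(frame)
  dropped <- frame[!complete, c("birth_year", "birth_month")]
  frame <- frame[complete, ]
  if (nrow(frame) == 0L)
    stop_ssr("no birth month has complete temperature coverage")
  if (nrow(dropped) > 0L)
    message("Dropped ", nrow(dropped), " of ", nrow(dropped) + nrow(frame),
            " birth months with incomplete temperature coverage")
  attr(frame, "dropped") <- dropped
  frame
}
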