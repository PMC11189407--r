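# Shared helpers: month arithmetic, lag-column naming, seeded evaluation.

LAGS <- -9:9

#' Names of the lagged-temperature columns
#'
#' Lag 0 is the conception month; negative lags are months before conception,
#' positive lags months after conception (all before birth). Columns are named
#' `lag_m9` ... `lag_m1`, `lag_0`, `lag_p1` ... `lag_p9`.
#'
#' @param lags Integer vector of lags (default `-9:9`).
#' @return Character vector of column names, same length as `lags`.
#' @export
lag_col_names <- function(lags = LAGS) {
  ifelse(lags < 0, paste0("lag_m", -lags),
         ifelse(lags > 0, paste0("lag_p", lags), "lag_0"))
}

# Shift (year, month) by k calendar months; vectorised.
month_shift <- function(year, month, k) {
  idx <- year * 12L + (month - 1L) + k
  list(year = idx %/% 12L, month = idx %% 12L + 1L)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ssr <- function(...) stop(..., call. = FALSE)
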