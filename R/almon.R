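# Almon polynomial distributed-lag sub-model: the 19 per-lag temperature
# coefficients are constrained to lie on a low-degree polynomial of the lag
# index, fitted through a reduced (d+1)-column design and back-transformed
# with delta-method pointwise confidence intervals.

#' Specify an Almon polynomial lag constraint
#'
#' @param degree Polynomial degree `d` (default 3); the lag-coefficient
#'   sequence is constrained to a degree-`d` polynomial of the lag index.
#'   `d = L - 1` (18 for the full window) reproduces the unconstrained
#'   distributed-lag fit.
#' @param lag_min,lag_max Lag window around the conception month (defaults
#'   -9 and +9; lag 0 = conception month).
#' @return An object of class `"almon_spec"`.
#' @export
almon_spec <- function(degree = 3L, lag_min = -9L, lag_max = 9L) {
  L <- lag_max - lag_min + 1L
  if (L < 2) stop_ssr("lag window must contain at least 2 lags")
  if (degree < 0 || degree > L - 1)
    stop_ssr("`degree` must lie in 0..", L - 1)
  structure(list(degree = as.integer(degree), lag_min = as.integer(lag_min),
                 lag_max = as.integer(lag_max), n_lags = L),
            class = "almon_spec")
}

#' Almon transform matrix
#'
#' Maps polynomial coefficients theta (length `d + 1`) to lag coefficients
#' `beta = T theta` (length `L`). Columns are an orthonormalized polynomial
#' basis in the lag index (re-centred to `0..L-1`), for conditioning; signs
#' are fixed so the matrix is deterministic.
#'
#' @param spec An [almon_spec()].
#' @return An `L x (d+1)` matrix with orthonormal columns.
#' @export
almon_transform <- function(spec) {
  stopifnot(inherits(spec, "almon_spec"))
  L <- spec$n_lags
  idx <- seq_len(L) - 1
  V <- outer(idx, 0:spec$degree, `^`)
  qrV <- qr(V)
  Tm <- qr.Q(qrV)
  # deterministic signs: diagonal of R positive
  signs <- sign(diag(qr.R(qrV)))
  signs[signs == 0] <- 1
  Tm <- sweep(Tm, 2, signs, `*`)
  rownames(Tm) <- as.character(seq(spec$lag_min, spec$lag_max))
  colnames(Tm) <- paste0("almon_", 0:spec$degree)
  Tm
}

#' Fold the lag-temperature block through the Almon constraint
#'
#' Multiplies the n x L matrix of lagged monthly temperatures by the Almon
#' transform, producing the `d + 1` reduced design columns that enter the
#' additive model as parametric terms.
#'
#' @param frame Model frame containing the 19 lag columns
#'   ([lag_col_names()]), complete (no missing cells).
#' @param spec An [almon_spec()].
#' @return An `n x (d+1)` numeric matrix with the transform attached as
#'   attribute `"transform"` and the spec as `"almon_spec"`.
#' @export
fold_lag_term <- function(frame, spec = almon_spec()) {
  cols <- lag_col_names(seq(spec$lag_min, spec$lag_max))
  missing_cols <- setdiff(cols, names(frame))
  if (length(missing_cols) > 0)
    stop_ssr("frame is missing lag columns: ",
             paste(missing_cols, collapse = ", "))
  Lmat <- as.matrix(frame[cols])
  if (anyNA(Lmat))
    stop_ssr("lag columns contain missing values; filter the frame first")
  Tm <- almon_transform(spec)
  reduced <- Lmat %*% Tm
  colnames(reduced) <- colnames(Tm)
  attr(reduced, "transform") <- Tm
  attr(reduced, "almon_spec") <- spec
  reduced
}

#' Recover per-lag coefficients from a fitted Almon block
#'
#' Back-transforms the fitted polynomial coefficients to the L per-lag
#' coefficients, `beta = T theta_hat`, with delta-method covariance
#' `T Cov(theta_hat) T'`, pointwise 95% confidence intervals
#' `beta_l +/- 1.96 SE_l` and a per-lag significance flag (0 outside the
#' interval).
#'
#' @param fit An [ssr_gam()] fit containing Almon reduced columns (as fitted
#'   by [fit_mta()]), or any fit whose parametric block includes columns named
#'   `almon_0..almon_d`.
#' @param spec The [almon_spec()] used to fold the block; defaults to the
#'   spec stored in the fit.
#' @return A tibble of class `"lag_table"`: `lag`, `coefficient`, `se`,
#'   `lower`, `upper`, `significant`. The full lag covariance is attached as
#'   attribute `"cov"`.
#' @export
recover_lag_coefficients <- function(fit, spec = NULL) {
  stopifnot(inherits(fit, "ssr_gam"))
  spec <- spec %||% fit$almon_spec
  if (is.null(spec)) stop_ssr("fit has no Almon block spec")
  Tm <- almon_transform(spec)
  cn <- names(fit$coefficients)
  idx <- match(colnames(Tm), cn)
  if (anyNA(idx))
    stop_ssr("fit does not contain the Almon columns ",
             paste(colnames(Tm)[is.na(idx)], collapse = ", "))
  theta <- fit$coefficients[idx]
  V_theta <- fit$Vp[idx, idx, drop = FALSE]
  if (anyNA(V_theta)) stop_ssr("missing covariance for the Almon block")
  beta <- as.numeric(Tm %*% theta)
  V_beta <- Tm %*% V_theta %*% t(Tm)
  se <- unname(sqrt(pmax(diag(V_beta), 0)))
  out <- tibble::tibble(
    lag = seq(spec$lag_min, spec$lag_max),
    coefficient = beta, se = se,
    lower = beta - 1.96 * se, upper = beta + 1.96 * se
  )
  out$significant <- out$lower > 0 | out$upper < 0
  attr(out, "cov") <- V_beta
  class(out) <- c("lag_table", class(out))
  out
}

#' Write a per-lag coefficient table
#'
#' Delimited text in the conventional distributed-lag report layout: lag,
#' coefficient, SE, lower and upper pointwise 95% limits, and a star for
#' significance.
#'
#' @param lag_table A [recover_lag_coefficients()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lag_table <- function(lag_table, path) {
  out <- tibble::as_tibble(lag_table)
  out$star <- ifelse(out$significant, "*", "")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Scan Almon polynomial degrees
#'
#' Refits the distributed-lag model at each candidate degree and reports
#' deviance, total effective degrees of freedom and AIC
#' (`deviance + 2 * edf`), supporting an explicit degree choice.
#'
#' @param frame Model frame from [assemble_model_frame()].
#' @param degrees Integer vector of degrees to try (default `1:6`).
#' @param ... Passed to [fit_mta()].
#' @return Tibble: `degree`, `deviance`, `edf_total`, `aic`.
#' @export
almon_degree_scan <- function(frame, degrees = 1:6, ...) {
  purrr::map_dfr(degrees, function(d) {
    fit <- fit_mta(frame, almon = almon_spec(degree = d), ...)
    tibble::tibble(degree = d, deviance = fit$deviance,
                   edf_total = fit$edf_total,
                   aic = fit$deviance + 2 * fit$edf_total)
  })
}
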