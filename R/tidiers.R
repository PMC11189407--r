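# broom-style tidiers for fitted models.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted additive model
#'
#' `type = "parametric"` returns one row per unpenalized coefficient
#' (estimate, SE, two-sided Wald p); `type = "smooth"` one row per smooth
#' term (effective degrees of freedom and the approximate Wald test).
#'
#' @param x An [ssr_gam()] fit.
#' @param type `"parametric"` or `"smooth"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ssr_gam
#' @export
tidy.ssr_gam <- function(x, type = c("parametric", "smooth"), ...) {
  type <- match.arg(type)
  if (type == "parametric") {
    cols <- x$design$term_map[["(parametric)"]]
    est <- x$coefficients[cols]
    se <- sqrt(diag(x$Vp)[cols])
    tibble::tibble(
      term = names(est), estimate = unname(est), se = unname(se),
      p_value = 2 * stats::pnorm(-abs(est / se))
    )
  } else {
    terms <- setdiff(names(x$design$term_map), "(parametric)")
    purrr::map_dfr(terms, function(t) {
      tt <- smooth_pvalue(x, t)
      tibble::tibble(term = t, edf = x$edf_by_term[[t]],
                     p_value = tt$p_value)
    })
  }
}

#' One-row model summary
#'
#' @param x An [ssr_gam()] fit.
#' @param ... Unused.
#' @return Tibble: model, n, deviance, null_deviance, edf_total, loglik,
#'   aic, criterion, converged.
#' @method glance ssr_gam
#' @export
glance.ssr_gam <- function(x, ...) {
  tibble::tibble(
    model = x$model_name %||% "custom",
    n = x$n,
    deviance = x$deviance,
    null_deviance = x$null_deviance,
    edf_total = x$edf_total,
    loglik = x$loglik,
    aic = x$deviance + 2 * x$edf_total,
    criterion = x$criterion,
    converged = x$converged
  )
}
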