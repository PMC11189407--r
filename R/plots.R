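# ggplot2 figures: effect curves with pointwise bands, the per-lag
# coefficient profile, and the thermal-classification heat map.

#' Plot a smooth effect curve
#'
#' Centred partial effect on the logit scale (or the implied girl
#' probability) over the covariate range, with the pointwise 95% band.
#'
#' @param fit An [ssr_gam()] fit.
#' @param term Smooth term name, e.g. `"s(temp_year_mean)"`.
#' @param scale `"logit"` or `"probability"`.
#' @return A ggplot object.
#' @export
plot_effect <- function(fit, term, scale = c("logit", "probability")) {
  scale <- match.arg(scale)
  eff <- predict_effect(fit, term, scale = scale)
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$x, y = .data$effect)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = attr(eff, "term"),
                  y = if (scale == "logit") "centred effect (logit)"
                      else "P(girl)") +
    ggplot2::theme_minimal()
}

#' @method autoplot ssr_gam
#' @export
autoplot.ssr_gam <- function(object, scale = "logit", ...) {
  terms <- setdiff(names(object$design$term_map), "(parametric)")
  effs <- purrr::map_dfr(terms, function(t) {
    e <- predict_effect(object, t, scale = scale)
    e$term <- t
    e
  })
  ggplot2::ggplot(effs, ggplot2::aes(x = .data$x, y = .data$effect)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "centred effect (logit)") +
    ggplot2::theme_minimal()
}

#' @method autoplot lag_table
#' @export
autoplot.lag_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$coefficient)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper,
                                          colour = .data$significant)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "lag (months from conception)",
                  y = "effect on logit P(girl) per degC") +
    ggplot2::theme_minimal()
}

#' Heat map of the percentile thermal classification
#'
#' Years on the horizontal axis, scopes (annual plus the 12 calendar months)
#' on the vertical axis, fill by the 11-band class index.
#'
#' @param classification Result of [classify_thermal()].
#' @return A ggplot object.
#' @export
plot_thermal_classes <- function(classification) {
  df <- tibble::as_tibble(classification)
  df$scope <- factor(df$scope,
                     levels = rev(c("annual", paste0("month_", 1:12))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$scope,
                                   fill = .data$class)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7",
                                  high = "#b2182b", midpoint = 6,
                                  limits = c(1, 11),
                                  name = "thermal class") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
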