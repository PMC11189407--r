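test_that("intercept-only fit equals the closed-form pooled logit", {
  frame <- tibble::tibble(girls = 32087L, boys = 33922L, total = 66009L)
  fit <- ssr_gam(frame)
  expect_equal(fit$coefficients[["(Intercept)"]], qlogis(32087 / 66009),
               tolerance = 1e-8)
  expect_equal(round(fit$coefficients[["(Intercept)"]], 4), -0.0556)
})

test_that("unpenalized fit matches an independent logistic regression", {
  frame <- make_frame(seed = 41)
  des <- ssrlag:::assemble_design(frame, ssrlag:::m0_smooths(8, 6))
  ours <- fit_pirls(des$X, des$penalties, c(0, 0), frame$girls, frame$total)
  oracle <- glm(cbind(girls, total - girls) ~ des$X - 1,
                family = binomial, data = frame)
  expect_true(ours$converged)
  expect_lt(max(abs(ours$beta - unname(coef(oracle)))), 1e-6)
  expect_equal(ours$deviance, deviance(oracle), tolerance = 1e-8)
})

test_that("heavy shrinkage collapses the model to the intercept", {
  frame <- make_frame(seed = 43)
  big <- fit_m0(frame, lambda = c(1e12, 1e12))
  flat <- ssr_gam(frame)
  expect_lt(max(abs(big$fitted - flat$fitted)), 1e-4)
  expect_lt(sum(effective_dof(big)[-1]), 1e-3)
})

test_that("model edf is non-increasing in each smoothing parameter", {
  frame <- make_frame(seed = 44)
  grid <- 10^seq(-2, 8, by = 2)
  edf_year <- vapply(grid, function(l)
    fit_m0(frame, lambda = c(l, 1))$edf_total, numeric(1))
  edf_month <- vapply(grid, function(l)
    fit_m0(frame, lambda = c(1, l))$edf_total, numeric(1))
  expect_true(all(diff(edf_year) < 1e-8))
  expect_true(all(diff(edf_month) < 1e-8))
})

test_that("aggregated and exploded per-birth fits coincide", {
  frame <- make_frame(seed = 45,
                      scenario = scenario_config(births_per_month = 12L,
                                                 seed = 46))
  frame <- frame[1:40, ]
  lam <- c(5, 5)
  smooths <- list(
    smooth_spec("birth_year", k = 4),
    smooth_spec("birth_month", k = 5, cyclic = TRUE,
                knots = seq(0.5, 12.5, length.out = 5)))
  agg <- ssr_gam(frame, smooths = smooths, lambda = lam)
  exploded <- frame[rep(seq_len(nrow(frame)), frame$total), ]
  exploded$girls <- unlist(lapply(seq_len(nrow(frame)), function(i)
    rep(c(1L, 0L), c(frame$girls[i], frame$total[i] - frame$girls[i]))))
  exploded$total <- 1L
  ind <- ssr_gam(exploded, smooths = smooths, lambda = lam)
  expect_lt(max(abs(agg$coefficients - ind$coefficients)), 1e-6)
})

test_that("the selected smoothing parameters minimise the criterion", {
  frame <- make_frame(seed = 47)
  des <- ssrlag:::assemble_design(frame, ssrlag:::m0_smooths(8, 6))
  sel <- select_smoothing(des$X, des$penalties, frame$girls, frame$total,
                          criterion = "REML")
  binfo <- ssrlag:::penalty_block_info(des$penalties)
  crit <- function(rho) ssrlag:::laml_criterion(
    rho, des$X, des$penalties, frame$girls, frame$total, binfo,
    ncol(des$X))$value
  v_opt <- crit(log(sel$lambda))
  set.seed(48)
  for (i in 1:10) {
    rho_pert <- log(sel$lambda) + rnorm(2, 0, 1.5)
    expect_gte(crit(rho_pert), v_opt - 1e-6)
  }
})

test_that("edf bookkeeping: parametric columns count 1, traces add up", {
  frame <- make_frame(seed = 49)
  fit <- fit_mta(frame)
  edf <- effective_dof(fit)
  # intercept + 4 Almon columns, all unpenalized
  expect_equal(unname(edf[["(parametric)"]]), 5, tolerance = 1e-8)
  expect_equal(sum(edf), fit$edf_total, tolerance = 1e-10)
  expect_true(all(edf >= -1e-8))
  expect_error(effective_dof(fit, "s(nope)"), "unknown term")
})

test_that("smooth p-values are probabilities and respond to signal", {
  frame <- make_frame(
    seed = 50,
    scenario = scenario_config(season_shape = 0.12 * sin(2 * pi * (1:12) / 12),
                               births_per_month = 500L, seed = 51))
  fit <- fit_m0(frame)
  tt <- smooth_pvalue(fit, "s(birth_month)")
  expect_true(tt$p_value >= 0 && tt$p_value <= 1)
  expect_lt(tt$p_value, 0.001)      # strong true season
  expect_error(smooth_pvalue(fit, "s(missing)"), "unknown smooth term")
})

test_that("effect curves are centred and their bands narrow with data", {
  sc_small <- scenario_config(births_per_month = 50L, seed = 53)
  sc_big <- scenario_config(births_per_month = 500L, seed = 53)
  f_small <- make_frame(seed = 52, scenario = sc_small)
  f_big <- make_frame(seed = 52, scenario = sc_big)
  fit_small <- fit_m0(f_small, lambda = c(10, 10))
  fit_big <- fit_m0(f_big, lambda = c(10, 10))
  eff <- predict_effect(fit_small, "s(birth_year)",
                        grid = f_small$birth_year)
  expect_lt(abs(mean(eff$effect)), 1e-6)   # sum-to-zero centring
  e1 <- predict_effect(fit_small, "s(birth_year)")
  e2 <- predict_effect(fit_big, "s(birth_year)")
  expect_true(all(e2$se < e1$se))
  expect_warning(predict_effect(fit_small, "s(birth_year)", grid = 2000),
                 "beyond the observed")
  expect_true(all(e1$upper >= e1$effect & e1$lower <= e1$effect))
})

test_that("a linear trend truth is recovered as a near-linear smooth", {
  # negative linear year effect on the logit scale
  sc <- scenario_config(lag_profile = rep(0, 19),
                        trend_shape = function(y) -0.004 * (y - 1874),
                        births_per_month = 1000L, seed = 55)
  temps <- simulate_temperature(climatology_profile(), seed = 54)
  births <- simulate_birth_series(temps, sc)
  frame <- suppressMessages(assemble_model_frame(births, temps))
  fit <- fit_m0(frame, shrink = FALSE)
  eff <- predict_effect(fit, "s(birth_year)")
  expect_true(all(diff(eff$effect) < 0))        # monotone decreasing
  edf_y <- effective_dof(fit, "s(birth_year)")
  expect_gt(edf_y, 0.6)
  expect_lt(edf_y, 1.6)                          # close to a straight line
  expect_lt(smooth_pvalue(fit, "s(birth_year)")$p_value, 0.001)
})

test_that("REML fits agree with the reference GAM implementation", {
  library(mgcv)
  frame <- make_frame(seed = 56, start_year = 1848, end_year = 1880)
  ours <- fit_m0(frame)
  ref <- mgcv::gam(cbind(girls, total - girls) ~
                     s(birth_year, bs = "cs", k = 10) +
                     s(birth_month, bs = "cc", k = 8),
                   knots = list(birth_month = seq(0.5, 12.5, length.out = 8)),
                   family = binomial, data = frame, method = "REML")
  expect_lt(sqrt(mean((ours$fitted - fitted(ref))^2)), 1e-3)
  expect_lt(abs(ours$deviance - deviance(ref)), 1)
})

test_that("non-convergence surfaces as a flagged warning, not silence", {
  frame <- make_frame(seed = 57)[1:30, ]
  des <- ssrlag:::assemble_design(
    frame, list(smooth_spec("birth_year", k = 3),
                smooth_spec("birth_month", k = 6, cyclic = TRUE,
                            knots = seq(0.5, 12.5, length.out = 6))))
  strained <- fit_pirls(des$X, des$penalties, c(1, 1), frame$girls,
                        frame$total, maxit = 1L)
  expect_false(strained$converged)
  expect_equal(strained$iterations, 1L)
})
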