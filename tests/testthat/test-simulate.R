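test_that("noise-free simulation reproduces the climatology exactly", {
  prof <- climatology_profile(monthly_sds = rep(0, 12), trend_per_decade = 0,
                              start_year = 1850, end_year = 1860)
  temps <- simulate_temperature(prof, seed = 1)
  jan <- temps$temp_c[temps$month == 1]
  expect_true(all(jan == -3.0))
  for (m in 1:12)
    expect_true(all(temps$temp_c[temps$month == m] == prof$monthly_means[m]))
  expect_equal(nrow(temps), 11 * 12)
})

test_that("linear trend contributes exact arithmetic and no cell is missing", {
  prof <- climatology_profile(monthly_means = rep(7, 12),
                              monthly_sds = rep(0, 12),
                              trend_per_decade = 1.0,
                              start_year = 1848, end_year = 1900)
  temps <- simulate_temperature(prof, seed = 1)
  t1848 <- temps$temp_c[temps$year == 1848]
  t1898 <- temps$temp_c[temps$year == 1898]
  expect_equal(t1898 - t1848, rep(5.0, 12))
  # complete grid
  expect_equal(nrow(dplyr::distinct(temps, year, month)), 53 * 12)
  expect_false(anyNA(temps$temp_c))
})

test_that("simulated annual means match the analytic generator mean", {
  # many replicate years, trend off so the implied annual mean is exact
  prof <- climatology_profile(trend_per_decade = 0, start_year = 1,
                              end_year = 4000)
  temps <- simulate_temperature(prof, seed = 99)
  ann <- tapply(temps$temp_c, temps$year, mean)
  implied <- mean(prof$monthly_means)
  se <- sqrt(sum(prof$monthly_sds^2) / 144) / sqrt(length(ann))
  expect_lt(abs(mean(ann) - implied), 3 * se)
})

test_that("temperature simulation is reproducible and seed-sensitive", {
  prof <- small_profile()
  a <- simulate_temperature(prof, seed = 7)
  b <- simulate_temperature(prof, seed = 7)
  c <- simulate_temperature(prof, seed = 8)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$temp_c, c$temp_c)))
})

test_that("profile validation rejects malformed climatologies", {
  expect_error(climatology_profile(monthly_means = rep(0, 11)), "12 values")
  expect_error(climatology_profile(monthly_sds = c(rep(1, 11), -1)),
               "non-negative")
  expect_error(climatology_profile(start_year = 1900, end_year = 1848),
               "precede")
})

test_that("true linear predictor matches a brute-force summation oracle", {
  frame <- make_frame(seed = 11)
  # additive identity
  sc0 <- scenario_config(lag_profile = rep(0, 19), baseline_logit = 0)
  expect_equal(true_linear_predictor(sc0, frame), rep(0, nrow(frame)))
  # single-term product
  lp <- rep(0, 19); lp[10] <- 0.01   # lag 0
  sc1 <- scenario_config(lag_profile = lp, baseline_logit = 0)
  row1 <- frame[1, ]
  row1[lag_col_names()] <- as.list(rep(0, 19))
  row1$lag_0 <- 10
  expect_equal(true_linear_predictor(sc1, row1), 0.1)
  # arbitrary scenario vs independent per-lag loop
  set.seed(42)
  sc <- scenario_config(lag_profile = rnorm(19, 0, 0.01),
                        trend_shape = function(y) 0.001 * (y - 1850),
                        season_shape = rnorm(12, 0, 0.05),
                        baseline_logit = -0.05)
  eta <- true_linear_predictor(sc, frame)
  for (i in c(1, 17, nrow(frame))) {
    acc <- sc$baseline_logit + sc$trend_shape(frame$birth_year[i]) +
      sc$season_shape[frame$birth_month[i]]
    for (j in 1:19)
      acc <- acc + sc$lag_profile[j] * frame[[lag_col_names(-9:9)[j]]][i]
    expect_equal(eta[i], acc, tolerance = 1e-12)
  }
  # missing lag temperature
  bad <- frame; bad$lag_0 <- NULL
  expect_error(true_linear_predictor(sc, bad), "lag_0")
})

test_that("birth simulation respects the binomial null and determinism", {
  temps <- simulate_temperature(small_profile(1848, 1880), seed = 3)
  sc <- scenario_config(lag_profile = rep(0, 19), baseline_logit = 0,
                        births_per_month = 4000L, seed = 4)
  births <- simulate_birth_series(temps, sc)
  expect_true(all(births$boys + births$girls == 4000L))
  n_tot <- sum(births$boys + births$girls)
  prop <- sum(births$girls) / n_tot
  expect_lt(abs(prop - 0.5), 3 * sqrt(0.25 / n_tot))
  expect_identical(births, simulate_birth_series(temps, sc))
})

test_that("pooled girl proportion tracks the inverse-logit of the baseline", {
  temps <- simulate_temperature(small_profile(1848, 1880), seed = 5)
  sc <- scenario_config(lag_profile = rep(0, 19), baseline_logit = -0.0556,
                        births_per_month = 4000L, seed = 6)
  births <- simulate_birth_series(temps, sc)
  n_tot <- sum(births$boys + births$girls)
  p_true <- plogis(-0.0556)  # ~0.4861
  expect_lt(abs(sum(births$girls) / n_tot - p_true),
            3 * sqrt(p_true * (1 - p_true) / n_tot))
})

test_that("per-month girl proportions converge to the true probabilities", {
  temps <- simulate_temperature(small_profile(1848, 1856), seed = 8)
  sc <- scenario_config(births_per_month = 100000L, seed = 9)
  births <- simulate_birth_series(temps, sc, years = 1850)
  frame <- suppressMessages(assemble_model_frame(births, temps))
  p_true <- plogis(true_linear_predictor(sc, frame))
  p_hat <- frame$girls / frame$total
  se <- sqrt(p_true * (1 - p_true) / frame$total)
  expect_true(all(abs(p_hat - p_true) < 4 * se))
})

test_that("insufficient temperature coverage is reported with the month", {
  temps <- simulate_temperature(small_profile(1850, 1855), seed = 10)
  sc <- scenario_config(seed = 11)
  expect_error(simulate_birth_series(temps, sc, years = 1850),
               "missing \\(1848, 7\\)")
  expect_error(
    simulate_birth_series(temps[temps$year > 1855, ], sc),
    "no complete lag window")
})
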