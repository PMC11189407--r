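test_that("climatology of a constant series is degenerate", {
  temps <- tibble::tibble(year = rep(1850:1859, each = 12L),
                          month = rep(1:12, 10), temp_c = 7.5)
  cs <- climatology_summary(temps)
  expect_true(all(cs$monthly$mean == 7.5))
  expect_true(all(cs$monthly$sd == 0))
  expect_equal(cs$overall$mean, 7.5)
  expect_equal(cs$overall$sd, 0)
})

test_that("two-year toy series matches the closed-form mean and sd", {
  temps <- tibble::tibble(year = rep(c(1850L, 1851L), each = 12L),
                          month = rep(1:12, 2),
                          temp_c = rep(c(6, 8), each = 12L))
  cs <- climatology_summary(temps)
  expect_equal(cs$annual$temp_annual, c(6, 8))
  expect_equal(cs$overall$mean, 7)
  expect_equal(cs$overall$sd, abs(8 - 6) / sqrt(2))  # two-point formula
})

test_that("incomplete years are excluded from the annual series with warning", {
  temps <- tibble::tibble(year = rep(c(1850L, 1851L), each = 12L),
                          month = rep(1:12, 2), temp_c = 5)
  temps <- temps[-15, ]  # drop one month of 1851
  expect_warning(cs <- climatology_summary(temps), "incomplete")
  expect_equal(cs$annual$year, 1850L)
})

test_that("an exact linear series yields the exact decadal slope", {
  annual <- tibble::tibble(year = 1848:1900,
                           temp_annual = 7.0 + 0.01 * (1848:1900 - 1848))
  tr <- suppressWarnings(linear_trend(annual))  # exact fit
  expect_equal(tr$slope_per_decade, 0.1, tolerance = 1e-10)
  expect_true(tr$significant)
  expect_error(linear_trend(annual[1:2, ]), "at least 3")
})

test_that("the trend t-test holds its size on white noise", {
  nrep <- 2000
  years <- 1848:1900
  set.seed(2024)
  rej <- vapply(seq_len(nrep), function(r) {
    ann <- tibble::tibble(year = years,
                          temp_annual = rnorm(length(years), 7.5, 0.8))
    linear_trend(ann)$p_value < 0.05
  }, logical(1))
  mc <- 3 * sqrt(0.05 * 0.95 / nrep)
  expect_gt(mean(rej), 0.05 - mc)
  expect_lt(mean(rej), 0.05 + mc)
})

test_that("percentile thresholds follow the interpolation quantile", {
  expect_equal(unname(percentile_thresholds(1:100, probs = 5)), 5.95)
  expect_equal(unname(percentile_thresholds(1:101, probs = 50)), 51)
  expect_true(all(percentile_thresholds(rep(3.2, 10)) == 3.2))
  thr <- percentile_thresholds(rnorm(200))
  expect_true(all(diff(thr) >= 0))
  expect_error(percentile_thresholds(numeric(0)), "at least 2")
  expect_error(percentile_thresholds(1:10, probs = c(10, 5)),
               "strictly increasing")
  expect_error(percentile_thresholds(1:10, probs = c(0, 50)),
               "strictly increasing|within")
})

test_that("class occupancy is proportional to the percentile band widths", {
  # 100 distinct annual values, one constant year each
  temps <- tibble::tibble(year = rep(1:100, each = 12L),
                          month = rep(1:12, 100),
                          temp_c = rep(as.numeric(1:100), each = 12L))
  cls <- classify_thermal(temps)
  ann <- cls[cls$scope == "annual", ]
  expect_equal(nrow(ann), 100L)
  occupancy <- tabulate(ann$class, nbins = 11)
  expected <- c(5, 5, 10, 10, 10, 20, 10, 10, 10, 5, 5)
  expect_true(all(abs(occupancy - expected) <= 1))
})

test_that("every scope-year gets one class, monotone in the value", {
  temps <- simulate_temperature(small_profile(1848, 1900), seed = 31)
  cls <- classify_thermal(temps)
  counts <- dplyr::count(tibble::as_tibble(cls), scope, year)
  expect_true(all(counts$n == 1L))
  expect_equal(nrow(counts), 13 * 53)
  for (sc in c("annual", "month_1", "month_7")) {
    sub <- cls[cls$scope == sc, ]
    expect_true(all(diff(sub$class[order(sub$value)]) >= 0))
  }
})

test_that("degenerate all-equal values land in the middle class", {
  temps <- tibble::tibble(year = rep(1850:1859, each = 12L),
                          month = rep(1:12, 10), temp_c = 7.5)
  cls <- classify_thermal(temps)
  expect_true(all(cls$class == 6L))
  expect_true(all(cls$label == "normal"))
})

test_that("classification is invariant under monotone transformation", {
  temps <- simulate_temperature(small_profile(1848, 1880), seed = 32)
  cls1 <- classify_thermal(temps)
  temps2 <- temps
  temps2$temp_c <- exp(temps2$temp_c / 10)
  cls2 <- classify_thermal(temps2)
  # annual scope is exempt (the annual mean is not equivariant), so compare
  # the monthly scopes where the transform acts value-wise
  for (m in 1:12) {
    a <- cls1[cls1$scope == paste0("month_", m), ]
    b <- cls2[cls2$scope == paste0("month_", m), ]
    expect_equal(a$class, b$class)
  }
})

test_that("the heat-map export is a scopes-by-years class table", {
  temps <- simulate_temperature(small_profile(1850, 1860), seed = 33)
  cls <- classify_thermal(temps)
  wide <- thermal_class_table(cls)
  expect_equal(nrow(wide), 13L)
  expect_equal(wide$scope[1], "annual")
  expect_equal(ncol(wide), 1L + 11L)
  path <- withr::local_tempfile(fileext = ".csv")
  thermal_class_table(cls, path)
  expect_true(file.exists(path))
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$`1855`, wide$`1855`)
})
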