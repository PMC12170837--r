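test_that("null lag effects leave prevalence independent of temperature tercile", {
  w <- simulate_country_weather(weather_config(start_year = 2022,
                                               end_year = 2023, seed = 5))
  cfg <- cohort_config(n_users = 300, nights_per_user = 365,
                       start_date = "2023-01-01", seasonal_amplitude = 0,
                       dow_effects = rep(0, 6), user_sd = 0, seed = 5)
  p <- simulate_cohort(w, cfg)
  terc <- cut(p$tmean, quantile(p$tmean, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  prev <- tapply(p$osa, terc, mean)
  se <- sqrt(0.254 * 0.746 / min(table(terc)))
  expect_lt(max(prev) - min(prev), 5 * se)
})

test_that("with all effects off, prevalence matches the baseline probability", {
  w <- simulate_country_weather(weather_config(start_year = 2022,
                                               end_year = 2023, seed = 8))
  cfg <- cohort_config(n_users = 300, nights_per_user = 340,
                       start_date = "2023-01-10", baseline_prob = 0.25,
                       seasonal_amplitude = 0, dow_effects = rep(0, 6),
                       user_sd = 0, seed = 8)
  p <- simulate_cohort(w, cfg)
  n <- nrow(p)
  expect_gt(n, 1e5)
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(mean(p$osa) - 0.25), 4 * se)
})

test_that("calibration reproduces the requested cumulative risk ratio exactly", {
  w <- simulate_country_weather(weather_config(start_year = 2023,
                                               end_year = 2023, seed = 2))
  cfg <- cohort_config(seed = 2)
  for (target in c(1.45, 1.49, 0.8, 2.5)) {
    cal <- calibrate_lag_effects(cfg, target, weather = w)
    expect_equal(generative_cumulative_rr(cal, 27.3, 6.4), target,
                 tolerance = 1e-12)
  }
  cal <- calibrate_lag_effects(cfg, 1.49, outcome = "severe", weather = w)
  expect_equal(generative_cumulative_rr(cal, 27.3, 6.4, "severe"), 1.49,
               tolerance = 1e-12)
  # calibration identity holds across the whole temperature grid:
  # RR(t1 vs t0) = exp(sum(theta) * (g(t1) - g(t0)))
  cal <- calibrate_lag_effects(cfg, 1.45, weather = w)
  grid <- seq(-2, 28, by = 2.5)
  for (t1 in grid) {
    rr <- generative_cumulative_rr(cal, t1, 6.4)
    expected <- exp(sum(cal$lag_effects) *
                      (exposure_transform(cal, t1) - exposure_transform(cal, 6.4)))
    expect_equal(rr, expected, tolerance = 1e-12)
  }
})

test_that("panels are pure functions of the seed and user streams are stable", {
  w <- simulate_country_weather(weather_config(start_year = 2023,
                                               end_year = 2023, seed = 4))
  cfg5 <- cohort_config(n_users = 5, nights_per_user = 60,
                        start_date = "2023-02-01", seed = 77)
  p1 <- simulate_cohort(w, cfg5)
  p2 <- simulate_cohort(w, cfg5)
  expect_identical(p1$osa, p2$osa)
  expect_identical(p1$tst, p2$tst)
  # enlarging the cohort leaves the first users' trajectories untouched
  cfg8 <- cohort_config(n_users = 8, nights_per_user = 60,
                        start_date = "2023-02-01", seed = 77)
  p3 <- simulate_cohort(w, cfg8)
  expect_identical(p3$osa[p3$user <= 5], p1$osa)
})

test_that("cohort dates outside weather coverage are rejected", {
  w <- simulate_country_weather(weather_config(start_year = 2023,
                                               end_year = 2023, seed = 1))
  cfg <- cohort_config(n_users = 2, nights_per_user = 30,
                       start_date = "2023-01-01", seed = 1)  # lags precede coverage
  expect_error(simulate_cohort(w, cfg), "max_lag preceding")
})

test_that("short-sleep missingness follows the 5-hour rule", {
  w <- simulate_country_weather(weather_config(start_year = 2023,
                                               end_year = 2023, seed = 6))
  cfg <- cohort_config(n_users = 120, nights_per_user = 300,
                       start_date = "2023-01-10", seed = 6)
  p <- simulate_cohort(w, cfg)

  p_all7 <- p; p_all7$tst <- 7
  expect_equal(sum(apply_missingness(p_all7)$miss_ahi), 0L)

  p_all4 <- p; p_all4$tst <- 4
  m4 <- apply_missingness(p_all4)
  expect_true(all(m4$miss_ahi))
  expect_true(all(is.na(m4$osa)))

  # TST ~ Normal(7.4, 0.8): missing fraction = Gaussian tail below 5 h
  m <- apply_missingness(p)
  expected <- pnorm(5, 7.4, 0.8)
  se <- sqrt(expected * (1 - expected) / nrow(p))
  expect_lt(abs(mean(m$miss_ahi) - expected), 5 * se)
})

test_that("temperature-dependent missingness concentrates on hot days", {
  w <- simulate_country_weather(weather_config(start_year = 2022,
                                               end_year = 2023, seed = 9))
  cfg <- cohort_config(n_users = 200, nights_per_user = 365,
                       start_date = "2023-01-01", seed = 9)
  p <- simulate_cohort(w, cfg)
  m <- apply_missingness(p, temperature_dependent = TRUE, slope = 0.3,
                         threshold = 20)
  hot <- p$tmean > 25
  expect_gt(mean(m$miss_ahi[hot]), mean(m$miss_ahi[!hot]))
})
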