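test_that("strata are participant/year/month cells", {
  p1 <- data.frame(user = 1, date = as.Date(c("2023-01-03", "2023-01-28")),
                   osa = c(1L, 0L))
  s1 <- assign_strata(p1)
  expect_equal(s1$stratum, c(1L, 1L))

  p2 <- data.frame(user = 1, date = as.Date(c("2023-01-31", "2023-02-01")),
                   osa = c(1L, 1L))
  expect_equal(assign_strata(p2)$stratum, c(1L, 2L))

  # 3 users x 3 months -> 9 strata
  p3 <- expand.grid(user = 1:3,
                    date = seq(as.Date("2023-01-01"), by = "day", length.out = 90))
  p3$osa <- 1L
  s3 <- assign_strata(p3)
  expect_equal(length(s3$n), 9L)

  # all-zero and all-missing strata flagged non-informative
  p4 <- data.frame(user = rep(1:2, each = 3),
                   date = rep(as.Date("2023-05-01") + 0:2, 2),
                   osa = c(1L, 0L, 1L, 0L, 0L, 0L))
  expect_equal(assign_strata(p4)$informative, c(TRUE, FALSE))
})

test_that("design matrix has the documented column layout", {
  w <- simulate_country_weather(weather_config(start_year = 2022,
                                               end_year = 2023, seed = 12,
                                               covariates = TRUE))
  cfg <- cohort_config(n_users = 10, nights_per_user = 120,
                       start_date = "2023-01-10", seed = 12)
  p <- simulate_cohort(w, cfg)
  covs <- c("cloud_cover", "rel_humidity", "pressure", "precipitation",
            "wind_speed", "pm25")
  for (cc in covs) p[[cc]] <- w[[cc]][match(p$date, w$date)]

  lagged <- cbind(p$tmean, as.matrix(p[, paste0("tlag", 1:4)]))
  spec <- crossbasis_spec(spline_spec_from_data(p$tmean, df = 4), max_lag = 4)
  cb <- cross_basis(lagged, spec)
  # cross-basis 20 + day-of-year 4 + day-of-week 6 + 7 covariates x 4 = 58
  X <- build_design(p, cb, covariates = c(covs, "tst"))
  expect_equal(ncol(X), 58L)
  g <- attr(X, "groups")
  expect_equal(g$crossbasis, 1:20)
  expect_equal(length(g$doy), 4L)
  expect_equal(length(g$dow), 6L)

  # column-group bookkeeping survives serialization
  X2 <- unserialize(serialize(X, NULL))
  expect_identical(attr(X2, "groups"), g)

  # a panel restricted to one weekday loses the day-of-week block
  p_mon <- p[format(p$date, "%u") == "1", ]
  cb_mon <- cross_basis(lagged[format(p$date, "%u") == "1", , drop = FALSE],
                        spec)
  expect_warning(X_mon <- build_design(p_mon, cb_mon), "single weekday")
  expect_null(attr(X_mon, "groups")$dow)

  # constant covariates are dropped with a warning
  p$flat <- 1
  expect_warning(build_design(p, cb, covariates = "flat"), "constant")
})

test_that("single-stratum conditional Poisson has the closed-form solution", {
  # x = 1: 3 events / 10 nights; x = 0: 1 event / 10 nights -> beta = log 3
  y <- c(rep(1, 3), rep(0, 7), rep(1, 1), rep(0, 9))
  x <- matrix(c(rep(1, 10), rep(0, 10)), ncol = 1,
              dimnames = list(NULL, "x"))
  f <- fit_conditional_poisson(y, x, rep(1L, 20))
  expect_equal(unname(f$coef), log(3), tolerance = 1e-8)
})

test_that("absorbed fit matches the explicit stratum-dummy Poisson oracle", {
  # 4-stratum toy panel
  set.seed(21)
  n <- 200
  strata <- sample(1:4, n, replace = TRUE)
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  eta <- -1.2 + 0.4 * x1 - 0.3 * x2 + c(0, 0.5, -0.4, 0.2)[strata]
  y <- rpois(n, exp(eta))
  X <- cbind(x1 = x1, x2 = x2)
  f <- fit_conditional_poisson(y, X, strata)
  oracle <- glm(y ~ x1 + x2 + factor(strata), family = poisson())
  expect_equal(unname(f$coef), unname(coef(oracle)[c("x1", "x2")]),
               tolerance = 1e-6)
  ov <- vcov(oracle)[c("x1", "x2"), c("x1", "x2")]
  expect_equal(unname(f$vcov), unname(ov), tolerance = 1e-5)

  # a wider panel with 50 strata
  set.seed(22)
  n <- 2000
  strata <- sample(1:50, n, replace = TRUE)
  X <- cbind(a = rnorm(n), b = runif(n), c = rbinom(n, 1, 0.3))
  y <- rpois(n, exp(-1 + X %*% c(0.3, -0.5, 0.2) + rnorm(50, 0, 0.3)[strata]))
  f <- fit_conditional_poisson(y, X, strata)
  oracle <- glm(y ~ X + factor(strata), family = poisson())
  expect_equal(unname(f$coef), unname(coef(oracle)[2:4]), tolerance = 1e-6)
})

test_that("zero-outcome strata do not affect the estimates", {
  set.seed(5)
  y <- rbinom(60, 1, 0.3)
  y[1:10] <- pmax(y[1:10], c(1, rep(0, 9)))  # ensure stratum 1 informative
  X <- matrix(rnorm(60), ncol = 1, dimnames = list(NULL, "x"))
  strata <- rep(1:3, each = 20)
  f1 <- fit_conditional_poisson(y, X, strata)
  # append a stratum whose outcome total is zero
  y2 <- c(y, rep(0, 15))
  X2 <- rbind(X, matrix(rnorm(15), ncol = 1))
  f2 <- fit_conditional_poisson(y2, X2, c(strata, rep(4L, 15)))
  expect_equal(f1$coef, f2$coef, tolerance = 1e-12)
  expect_equal(f2$n_dropped_strata, 1L)
})

test_that("cumulative RR contrasts are invariant to exposure translation", {
  sim <- make_small_panel(n_users = 30, nights = 200, seed = 33,
                          target_rr = 1.5)
  p <- sim$panel
  f1 <- fit_ctseries(p)
  cv1 <- cumulative_curve(f1)
  shift <- 7.5
  p2 <- p
  p2$tmean <- p$tmean + shift
  for (l in 1:4) p2[[paste0("tlag", l)]] <- p[[paste0("tlag", l)]] + shift
  es <- sim$cfg$exposure_spec
  es2 <- spline_spec(knots = es$knots + shift, boundary = es$boundary + shift,
                     center = es$center + shift)
  attr(p2, "exposure_spec") <- es2
  attr(p2, "doy_spec") <- attr(p, "doy_spec")
  f2 <- fit_ctseries(p2)
  cv2 <- cumulative_curve(f2)
  c1 <- rr_contrast(cv1, 20, 5)
  c2 <- rr_contrast(cv2, 20 + shift, 5 + shift)
  expect_equal(c1$rr, c2$rr, tolerance = 1e-6)
  expect_equal(c1$ci, c2$ci, tolerance = 1e-6)
})

test_that("minimum and maximum daily temperature work as sensitivity exposures", {
  sim <- make_small_panel(n_users = 15, nights = 120, seed = 48,
                          target_rr = 1.5)
  for (expo in c("tmin", "tmax")) {
    f <- fit_ctseries(sim$panel, exposure = expo, exposure_spec = spline_spec())
    expect_true(f$converged)
    # the fixed diurnal half-range shifts the exposure by a constant, so the
    # cumulative contrast between shifted temperatures matches the tmean fit
    expect_equal(length(f$cb_cols), 20L)
  }
})

test_that("rows with missing outcome are excluded as complete cases", {
  sim <- make_small_panel(n_users = 20, nights = 150, seed = 44)
  p <- apply_missingness(sim$panel)
  f <- fit_ctseries(p)
  expect_lte(f$n, sum(!is.na(p$osa)))
  expect_true(f$converged)
})

test_that("subgroup fitting partitions and skips as documented", {
  sim <- make_small_panel(n_users = 40, nights = 150, seed = 55,
                          target_rr = 1.6)
  p <- sim$panel

  # one level: identical to the global fit
  fits <- fit_subgroup(p, rep("all", nrow(p)), min_users = 5)
  global <- fit_ctseries(p)
  expect_equal(fits[["all"]]$coef, global$coef, tolerance = 1e-10)

  # a too-small group is skipped with a reason
  g <- ifelse(p$user <= 2, "tiny", "rest")
  fits2 <- fit_subgroup(p, g, min_users = 5)
  expect_named(attr(fits2, "skipped"), "tiny")
  expect_false("tiny" %in% names(fits2))

  expect_error(fit_subgroup(p[0, ], character(0)), "empty group")
})

test_that("subgroups with different true risk ratios are ordered correctly", {
  w <- simulate_country_weather(weather_config(start_year = 2022,
                                               end_year = 2023, seed = 66))
  cfg_lo <- calibrate_lag_effects(
    cohort_config(n_users = 120, nights_per_user = 365,
                  start_date = "2023-01-01", seed = 61), 1.1, weather = w)
  cfg_hi <- calibrate_lag_effects(
    cohort_config(n_users = 120, nights_per_user = 365,
                  start_date = "2023-01-01", seed = 62), 2.2, weather = w)
  p_lo <- simulate_cohort(w, cfg_lo)
  p_hi <- simulate_cohort(w, cfg_hi)
  p_hi$user <- p_hi$user + 1000
  p <- rbind(p_lo, p_hi)
  attr(p, "exposure_spec") <- cfg_lo$exposure_spec
  g <- ifelse(p$user > 1000, "high", "low")
  fits <- fit_subgroup(p, g, min_users = 10)
  rr <- vapply(fits, function(f) {
    rr_contrast(cumulative_curve(f), 27.3, 6.4)$rr
  }, numeric(1))
  expect_gt(rr[["high"]], rr[["low"]])
})
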