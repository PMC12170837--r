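mk_excess <- function(mean_excess = 0.05, year = 2023) {
  structure(list(year = year, values = rep(mean_excess, 365),
                 sum = mean_excess * 365, mean = mean_excess, n_clipped = 0L),
            class = "excess_series")
}

test_that("years of life lost follow the published arithmetic", {
  bp <- burden_params()
  cp <- test_country(p0 = 0.2, apop = 1e7, mva_death_rate = 2e-7, rle = 30)
  ex <- mk_excess(0.05)
  expect_equal(years_of_life_lost(ex, cp, bp, "mean"),
               0.05 * 0.2 * 1e7 * 2e-7 * 30)  # = 0.6 years
  expect_equal(years_of_life_lost(mk_excess(0), cp, bp, "mean"), 0)
  # linearity in the MVA risk ratio: lower bound is exactly half the mean
  expect_equal(years_of_life_lost(ex, cp, bp, "lower") /
                 years_of_life_lost(ex, cp, bp, "mean"), 0.5)
})

test_that("years lived with disability scale with the disability weight", {
  bp <- burden_params()
  cp <- test_country()
  ex <- mk_excess(0.03)
  bp0 <- burden_params(dw = c(0, 0, 0))
  expect_equal(years_lived_disability(ex, cp, bp0, "mean"), 0)
  expect_equal(years_lived_disability(ex, cp, bp, "lower") /
                 years_lived_disability(ex, cp, bp, "mean"), 0.625)
})

test_that("parametric bound construction reproduces the printed intervals", {
  # UK year-2023 YLL: mean 1,024 with RR triplet (0.5, 1, 1.5) -> lower 512
  expect_equal(unname(uncertainty_bounds(1024, c(0.5, 1, 1.5))),
               c(512, 1024, 1536))
  # 29-country YLL: 27,180 -> lower 13,590
  expect_equal(uncertainty_bounds(27180, c(0.5, 1, 1.5))[["lower"]], 13590)
  # UK YLD 58,341 with DW (0.05, 0.08, 0.11) -> lower 36,463 (to the integer)
  expect_equal(round(uncertainty_bounds(58341, c(0.05, 0.08, 0.11))[["lower"]]),
               36463)
  expect_equal(unname(uncertainty_bounds(7, c(1, 1, 1))), c(7, 7, 7))
  expect_error(uncertainty_bounds(1, c(0, 0, 0)), "nonzero")
})

test_that("DALYs are the exact sum of YLL and YLD", {
  # UK 2023: 58,341 YLD + 1,024 YLL = 59,365 DALYs
  expect_equal(daly(1024, 58341), 59365)
  expect_equal(daly(0, 0), 0)
  # additivity across countries
  expect_equal(daly(10, 20) + daly(5, 15), daly(15, 35))
})

test_that("wellbeing cost uses the GDP multiplier triplet", {
  bp <- burden_params()
  expect_equal(wellbeing_cost(1000, 5e4, bp, "mean"), 1e8)
  expect_equal(wellbeing_cost(1000, 5e4, bp, "lower") /
                 wellbeing_cost(1000, 5e4, bp, "mean"), 0.5)
  # the 29-country wellbeing cost: mean 68 billion -> lower 34 billion
  expect_equal(68e9 * (1 / 2), 34e9)
  expect_equal(uncertainty_bounds(68, c(1, 2, 3))[["lower"]], 34)
})

test_that("part-time adjustment halves part-time workers", {
  expect_equal(adjusted_labor_force(1000, 0), 1000)
  expect_equal(adjusted_labor_force(1000, 1), 500)
  expect_equal(adjusted_labor_force(1000, 0.2), 900)
})

test_that("productivity days follow the working-day equations", {
  bp <- burden_params()
  cp <- test_country(p0 = 0.25, labor_force = 1e6, pt_share = 0)
  ex <- mk_excess(10 / 365)   # sum of excess = 10
  pd <- productivity_days(ex, cp, bp)
  expect_equal(pd[["presenteeism"]], (235 / 365) * 10 * 0.25 * 1e6 * 0.068)
  expect_equal(pd[["absenteeism"]], (235 / 365) * 10 * 0.25 * 1e6 * 0.021)
  # the ratio is exactly 6.8 / 2.1 whatever the inputs
  expect_equal(pd[["presenteeism"]] / pd[["absenteeism"]], 6.8 / 2.1)
  bp0 <- burden_params(presenteeism_rate = 0, absenteeism_rate = 0)
  expect_equal(unname(productivity_days(ex, cp, bp0)), c(0, 0))
})

test_that("labor loss converts lost days through GDP per capita employed", {
  ll <- labor_loss(365, 0, 73000)
  expect_equal(ll$loss, 73000)
  expect_equal(ll$total_days, 365)
  expect_equal(labor_loss(0, 0, 5e4)$loss, 0)
  # 2023, 29 countries: 80M presenteeism + 25M absenteeism ~ 105M days
  expect_equal(labor_loss(80e6, 25e6, 0)$total_days, 105e6)
  # and wellbeing (68B) + productivity (30B) costs total ~98 billion USD
  expect_equal(68e9 + 30e9, 98e9)
})

test_that("a full-year burden row satisfies the DALY decomposition at all levels", {
  cp <- test_country()
  ex <- mk_excess(0.04)
  br <- burden_for_year(ex, cp)
  for (lev in c("lower", "mean", "upper")) {
    expect_equal(br[[paste0("daly_", lev)]],
                 br[[paste0("yll_", lev)]] + br[[paste0("yld_", lev)]])
  }
  expect_true(br$yll_lower <= br$yll_mean && br$yll_mean <= br$yll_upper)
  expect_true(br$cost_lower <= br$cost_mean && br$cost_mean <= br$cost_upper)
})

test_that("burden outputs are homogeneous of degree one in population and labor force", {
  ex <- mk_excess(0.06)
  cp1 <- test_country()
  cp2 <- test_country(apop = 2 * cp1$apop, labor_force = 3 * cp1$labor_force)
  b1 <- burden_for_year(ex, cp1)
  b2 <- burden_for_year(ex, cp2)
  for (col in c("person_days", "yll_mean", "yld_mean", "daly_mean", "cost_mean")) {
    expect_equal(b2[[col]], 2 * b1[[col]])
  }
  for (col in c("presenteeism_mean", "absenteeism_mean", "labor_loss_mean")) {
    expect_equal(b2[[col]], 3 * b1[[col]])
  }
})

test_that("bound ordering holds on randomized inputs", {
  set.seed(77)
  for (i in 1:25) {
    ex <- mk_excess(runif(1, 0, 0.2))
    cp <- test_country(p0 = runif(1, 0.05, 0.5), apop = runif(1, 1e5, 1e8),
                       labor_force = runif(1, 1e4, 1e7),
                       pt_share = runif(1), gdp_pc = runif(1, 1e3, 1e5))
    br <- burden_for_year(ex, cp)
    for (q in c("yll", "yld", "daly", "cost")) {
      expect_true(br[[paste0(q, "_lower")]] <= br[[paste0(q, "_mean")]] &&
                    br[[paste0(q, "_mean")]] <= br[[paste0(q, "_upper")]])
    }
  }
})

test_that("scenario projection is zero for a scenario equal to the climatology", {
  s <- constant_series(12, 1950, 2030)
  cl <- climatology_1950_1990(s)
  curve <- toy_curve(temp = c(0, 10, 20, 30), log_rr = c(-0.2, 0, 0.3, 0.6),
                     ref = 10)
  traj <- project_scenario(curve, s, cl, test_country(), years = 2024:2030,
                           envelope = FALSE)
  expect_equal(nrow(traj), 7L)
  expect_true(all(traj$daly_mean == 0))
  expect_true(all(traj$labor_loss_mean == 0))
  expect_equal(unname(attr(traj, "cumulative")[["person_days"]]), 0)
})

test_that("a uniformly warmer scenario yields non-negative burden every year", {
  dates <- seq(as.Date("1950-01-01"), as.Date("2040-12-31"), by = "day")
  yr <- as.integer(format(dates, "%Y"))
  s <- validate_daily_series(
    data.frame(date = dates, tmean = 12 + pmax(0, (yr - 1990) * 0.05)))
  cl <- climatology_1950_1990(s)
  curve <- toy_curve(temp = c(0, 10, 20, 30), log_rr = c(-0.2, 0, 0.3, 0.6),
                     ref = 10)
  traj <- project_scenario(curve, s, cl, test_country(), years = 2024:2040,
                           envelope = FALSE)
  expect_true(all(traj$daly_mean >= 0))
  expect_true(all(diff(traj$person_days) >= 0))
})

test_that("sensitivity mode factors into prevalence ramp times population ratio", {
  dates <- seq(as.Date("1950-01-01"), as.Date("2060-12-31"), by = "day")
  yr <- as.integer(format(dates, "%Y"))
  s <- validate_daily_series(
    data.frame(date = dates, tmean = 12 + pmax(0, (yr - 1990) * 0.04)))
  cl <- climatology_1950_1990(s)
  curve <- toy_curve(temp = c(0, 10, 20, 30), log_rr = c(-0.2, 0, 0.3, 0.6),
                     ref = 10)
  fc <- data.frame(year = 2023:2060, apop = 1e7 * (1 + 0.004 * (2023:2060 - 2023)))
  cp <- test_country(apop = 1e7, pop_forecast = fc)
  fixed <- project_scenario(curve, s, cl, cp, years = c(2050, 2055),
                            mode = "fixed", envelope = FALSE)
  sens <- project_scenario(curve, s, cl, cp, years = c(2050, 2055),
                           mode = "sensitivity", envelope = FALSE)
  for (k in 1:2) {
    y <- c(2050, 2055)[k]
    pop_ratio <- fc$apop[fc$year == y] / 1e7
    for (col in c("person_days", "yll_mean", "yld_mean", "daly_mean")) {
      expect_equal(sens[[col]][k], fixed[[col]][k] * 1.3 * pop_ratio,
                   tolerance = 1e-12)
    }
    # labor force is not forecast: productivity scales by the ramp only
    expect_equal(sens$presenteeism_mean[k], fixed$presenteeism_mean[k] * 1.3,
                 tolerance = 1e-12)
  }
  expect_error(project_scenario(curve, s, cl, test_country(),
                                years = c(2050, 2055), mode = "sensitivity"),
               "pop_forecast")
  expect_error(project_scenario(curve, s, cl, cp, years = 2070), "cover")
})
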