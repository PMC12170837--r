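#' Country-level parameters for burden calculation
#'
#' All country scalars entering the burden equations: OSA prevalence, adult
#' population, the daily fatal motor-vehicle-accident (MVA) death rate and
#' the residual life expectancy lost per MVA death (both from burden-of-
#' disease sources), the labor force and its part-time share, and GDP per
#' capita (overall, valuing wellbeing) and per capita employed (valuing work
#' days).
#'
#' @param label Country label.
#' @param p0 OSA prevalence, fraction in `[0, 1]`.
#' @param apop Adult population (persons).
#' @param mva_death_rate Fatal MVA death rate (deaths per person per day).
#' @param rle Residual life expectancy per MVA death (years).
#' @param labor_force Labor force (persons, before part-time adjustment).
#' @param pt_share Part-time employment share, fraction in `[0, 1]`.
#' @param gdp_pc GDP per capita (USD).
#' @param gdp_pc_employed GDP per capita employed (USD).
#' @param pop_forecast Optional `data.frame(year, apop)` used by the
#'   sensitivity projection mode.
#' @return An object of class `country_params`.
#' @export
country_params <- function(label, p0, apop, mva_death_rate, rle,
                           labor_force, pt_share, gdp_pc, gdp_pc_employed,
                           pop_forecast = NULL) {
  assert_prob(p0, "p0"); assert_prob(pt_share, "pt_share")
  for (nm in c("apop", "mva_death_rate", "rle", "labor_force", "gdp_pc",
               "gdp_pc_employed")) {
    v <- get(nm)
    stop_if(!is.finite(v) || v < 0, sprintf("'%s' must be >= 0", nm))
  }
  structure(list(label = label, p0 = p0, apop = apop,
                 mva_death_rate = mva_death_rate, rle = rle,
                 labor_force = labor_force, pt_share = pt_share,
                 gdp_pc = gdp_pc, gdp_pc_employed = gdp_pc_employed,
                 pop_forecast = pop_forecast),
            class = "country_params")
}

#' Burden model parameters with uncertainty triplets
#'
#' Uncertainty for the wellbeing outputs is parametric: the lower/mean/upper
#' triplets of the MVA risk ratio for OSA (0.5/1.0/1.5), the disability
#' weight (0.05/0.08/0.11), and the DALY monetary value (1/2/3 times GDP per
#' capita). Impairment duration is 1 day; a working year has 235 days; the
#' presenteeism and absenteeism rates are 6.8% and 2.1% of working days.
#'
#' @param rr_mva Length-3 MVA risk-ratio triplet (lower, mean, upper).
#' @param dw Length-3 disability-weight triplet.
#' @param impairment_days Impairment duration per affected day (days).
#' @param daly_value_multiplier Length-3 multiplier of GDP per capita.
#' @param working_days Working days per full-time worker per year.
#' @param presenteeism_rate,absenteeism_rate Fractions of working days.
#' @return An object of class `burden_params`.
#' @export
burden_params <- function(rr_mva = c(0.5, 1, 1.5),
                          dw = c(0.05, 0.08, 0.11),
                          impairment_days = 1,
                          daly_value_multiplier = c(1, 2, 3),
                          working_days = 235,
                          presenteeism_rate = 0.068,
                          absenteeism_rate = 0.021) {
  chk_trip <- function(x, nm) {
    stop_if(length(x) != 3L || is.unsorted(x),
            sprintf("'%s' must be an ordered (lower, mean, upper) triplet", nm))
  }
  chk_trip(rr_mva, "rr_mva"); chk_trip(dw, "dw")
  chk_trip(daly_value_multiplier, "daly_value_multiplier")
  assert_prob(presenteeism_rate, "presenteeism_rate")
  assert_prob(absenteeism_rate, "absenteeism_rate")
  structure(list(rr_mva = rr_mva, dw = dw, impairment_days = impairment_days,
                 daly_value_multiplier = daly_value_multiplier,
                 working_days = working_days,
                 presenteeism_rate = presenteeism_rate,
                 absenteeism_rate = absenteeism_rate),
            class = "burden_params")
}

level_index <- function(level) {
  level <- match.arg(level, c("lower", "mean", "upper"))
  c(lower = 1L, mean = 2L, upper = 3L)[[level]]
}

#' Years of life lost to warming-related OSA
#'
#' `YLL = (1/365) * sum over days of excess_d * p0 * APOP *
#' (MVA_death_rate * RR_MVA[level]) * RLE`, exactly the published form: the
#' annual mean of the daily excess risk times prevalent OSA population,
#' times the OSA-attributable daily fatal-MVA rate, times the residual life
#' expectancy per death.
#'
#' @param excess An `excess_series`.
#' @param cp A [country_params()].
#' @param bp A [burden_params()].
#' @param level `"lower"`, `"mean"` or `"upper"` (scales `rr_mva`).
#' @return Years of life lost.
#' @export
years_of_life_lost <- function(excess, cp, bp, level = "mean") {
  i <- level_index(level)
  excess$mean * cp$p0 * cp$apop * (cp$mva_death_rate * bp$rr_mva[i]) * cp$rle
}

#' Years lived with disability from warming-related OSA
#'
#' `YLD = (1/365) * sum over days of excess_d * p0 * APOP * DW[level] * L`,
#' with disability weight `DW` and impairment duration `L` (1 day).
#'
#' @inheritParams years_of_life_lost
#' @return Years lived with disability.
#' @export
years_lived_disability <- function(excess, cp, bp, level = "mean") {
  i <- level_index(level)
  excess$mean * cp$p0 * cp$apop * bp$dw[i] * bp$impairment_days
}

#' Disability-adjusted life years
#'
#' `DALY = YLL + YLD` (exact sum, any matching bound level).
#'
#' @param yll,yld Years of life lost / lived with disability.
#' @return DALYs.
#' @export
daly <- function(yll, yld) yll + yld

#' Monetary value of the wellbeing burden
#'
#' Values each DALY at a multiple of GDP per capita: 1x (lower), 2x (mean),
#' 3x (upper). The DALY input is held at its mean level; only the multiplier
#' moves across bounds.
#'
#' @param daly DALYs (mean level).
#' @param gdp_pc GDP per capita (USD).
#' @param bp A [burden_params()].
#' @param level Bound level selecting the multiplier.
#' @return USD.
#' @export
wellbeing_cost <- function(daly, gdp_pc, bp = burden_params(), level = "mean") {
  i <- level_index(level)
  daly * bp$daly_value_multiplier[i] * gdp_pc
}

#' Part-time-adjusted labor force
#'
#' Counts part-time workers as half a full-time equivalent:
#' `LF_adj = LF - LF * pt_share / 2`.
#'
#' @param lf Labor force (persons).
#' @param pt_share Part-time employment share in `[0, 1]`.
#' @return Adjusted labor force (full-time-equivalent persons).
#' @export
adjusted_labor_force <- function(lf, pt_share) {
  assert_prob(pt_share, "pt_share")
  lf - lf * pt_share / 2
}

#' Presenteeism and absenteeism days
#'
#' `PRES = (NWD/365) * sum over days of excess_d * p0 * LF_adj * PRES_rate`
#' (and absenteeism analogously): the excess OSA person-days among the
#' (part-time-adjusted) labor force, scaled to working days and multiplied
#' by the daily presenteeism (6.8%) or absenteeism (2.1%) rate.
#'
#' @param excess An `excess_series`.
#' @param cp A [country_params()].
#' @param bp A [burden_params()].
#' @param adjust_part_time Apply [adjusted_labor_force()] to `cp$labor_force`
#'   first (set `FALSE` if it is already adjusted).
#' @return Named numeric: `presenteeism`, `absenteeism` (days).
#' @export
productivity_days <- function(excess, cp, bp = burden_params(),
                              adjust_part_time = TRUE) {
  lf <- if (adjust_part_time) {
    adjusted_labor_force(cp$labor_force, cp$pt_share)
  } else {
    cp$labor_force
  }
  base <- (bp$working_days / 365) * excess$sum * cp$p0 * lf
  c(presenteeism = base * bp$presenteeism_rate,
    absenteeism = base * bp$absenteeism_rate)
}

#' Labor loss in USD
#'
#' `LL = (PRES + ABS) * GDP per capita employed / 365`.
#'
#' @param pres,abs_days Presenteeism and absenteeism days.
#' @param gdp_pc_employed GDP per capita employed (USD).
#' @return List: `loss` (USD), `total_days` (`pres + abs_days`).
#' @export
labor_loss <- function(pres, abs_days, gdp_pc_employed) {
  stop_if(gdp_pc_employed < 0, "'gdp_pc_employed' must be non-negative")
  # negative day counts are allowed: they arise when a cooler-than-baseline
  # year (or the lower CI envelope) reduces the burden
  list(loss = (pres + abs_days) * gdp_pc_employed / 365,
       total_days = pres + abs_days)
}

#' Parametric uncertainty bounds for a linear quantity
#'
#' For a quantity linear in a parameter with (lower, mean, upper) values,
#' the bounds are the mean-level point estimate rescaled by the parameter
#' ratios: `point * lower/mean`, `point`, `point * upper/mean`.
#'
#' @param point_at_mean Point estimate computed at the parameter's mean.
#' @param triplet Ordered (lower, mean, upper) parameter values; mean != 0.
#' @return Named numeric (lower, mean, upper).
#' @export
uncertainty_bounds <- function(point_at_mean, triplet) {
  stop_if(length(triplet) != 3L || is.unsorted(triplet),
          "'triplet' must be ordered (lower, mean, upper)")
  stop_if(triplet[2] == 0, "parameter mean must be nonzero")
  c(lower = point_at_mean * triplet[1] / triplet[2],
    mean = point_at_mean,
    upper = point_at_mean * triplet[3] / triplet[2])
}

#' Full burden result for one country-year
#'
#' Chains the burden equations for one excess-risk series: YLL and YLD with
#' their parametric bounds, DALY = YLL + YLD at each bound level, wellbeing
#' cost via the DALY-value multipliers, and the productivity block
#' (presenteeism/absenteeism days and labor loss). When lower/upper excess
#' series evaluated at the exposure-response curve's 95% CI envelope are
#' supplied, the productivity outputs inherit those bounds (their only
#' uncertainty source here).
#'
#' @param excess An `excess_series` at the curve's point estimate.
#' @param cp A [country_params()].
#' @param bp A [burden_params()].
#' @param excess_lower,excess_upper Optional `excess_series` at the curve CI
#'   envelope.
#' @return A one-row `data.frame` with columns `<quantity>_<level>`.
#' @export
burden_for_year <- function(excess, cp, bp = burden_params(),
                            excess_lower = NULL, excess_upper = NULL) {
  yll <- uncertainty_bounds(years_of_life_lost(excess, cp, bp, "mean"),
                            bp$rr_mva)
  yld <- uncertainty_bounds(years_lived_disability(excess, cp, bp, "mean"),
                            bp$dw)
  dal <- daly(yll, yld)
  cost <- vapply(c("lower", "mean", "upper"),
                 function(l) wellbeing_cost(dal[["mean"]], cp$gdp_pc, bp, l),
                 numeric(1))
  prod_at <- function(e) {
    pd <- productivity_days(e, cp, bp)
    ll <- labor_loss(pd[["presenteeism"]], pd[["absenteeism"]],
                     cp$gdp_pc_employed)
    c(pres = pd[["presenteeism"]], abs = pd[["absenteeism"]],
      loss = ll$loss, days = ll$total_days)
  }
  pm <- prod_at(excess)
  pl <- if (!is.null(excess_lower)) prod_at(excess_lower) else pm * NA
  pu <- if (!is.null(excess_upper)) prod_at(excess_upper) else pm * NA
  data.frame(
    year = excess$year,
    person_days = excess_person_days(excess, cp$p0, cp$apop),
    yll_lower = yll[["lower"]], yll_mean = yll[["mean"]],
    yll_upper = yll[["upper"]],
    yld_lower = yld[["lower"]], yld_mean = yld[["mean"]],
    yld_upper = yld[["upper"]],
    daly_lower = dal[["lower"]], daly_mean = dal[["mean"]],
    daly_upper = dal[["upper"]],
    cost_lower = cost[["lower"]], cost_mean = cost[["mean"]],
    cost_upper = cost[["upper"]],
    presenteeism_lower = pl[["pres"]], presenteeism_mean = pm[["pres"]],
    presenteeism_upper = pu[["pres"]],
    absenteeism_lower = pl[["abs"]], absenteeism_mean = pm[["abs"]],
    absenteeism_upper = pu[["abs"]],
    labor_loss_lower = pl[["loss"]], labor_loss_mean = pm[["loss"]],
    labor_loss_upper = pu[["loss"]],
    lost_days_mean = pm[["days"]]
  )
}

# Excess series evaluated at the curve's 95% CI envelope (z = 1.959964).
excess_at_envelope <- function(curve, year_series, clim, year, side, clip = TRUE) {
  z <- 1.959964 * if (side == "lower") -1 else 1
  shifted <- curve
  shifted$log_rr <- curve$log_rr + z * sqrt(pmax(curve$var, 0))
  shifted$var <- curve$var
  attr(shifted, "coef") <- NULL  # envelope curve is grid-only by construction
  attr(shifted, "vcov") <- NULL
  daily_excess_risk(shifted, year_series, clim, year = year, clip = clip)
}

#' Project the burden over a warming scenario
#'
#' Runs the attribution-to-burden chain for every year of a daily scenario
#' series: daily excess risk against the fixed 1950-1990 climatology, then
#' the burden equations. The primary mode holds OSA prevalence and adult
#' population at their (2023) values for the whole horizon; the sensitivity
#' mode applies the country population forecast and ramps prevalence
#' linearly to 1.3x between `ramp_from` (2023) and `ramp_to` (2050), holding
#' it constant afterwards.
#'
#' @param curve An `exposure_response_curve`.
#' @param scenario A `daily_series` covering every projection year fully.
#' @param clim A [climatology_1950_1990()] result.
#' @param cp A [country_params()] (2023 values; `pop_forecast` required for
#'   the sensitivity mode).
#' @param bp A [burden_params()].
#' @param years Years to project (default all complete years in `scenario`).
#' @param mode `"fixed"` (primary) or `"sensitivity"`.
#' @param prevalence_increase Total relative increase reached at `ramp_to`
#'   (0.3 = +30%).
#' @param ramp_from,ramp_to Calendar years bounding the prevalence ramp.
#' @param envelope Also evaluate the curve's CI envelope to bound the
#'   productivity outputs.
#' @return A `data.frame` of class `scenario_trajectory`, one row per year,
#'   with attribute `"cumulative"` holding the horizon sums of the mean-level
#'   outputs.
#' @export
project_scenario <- function(curve, scenario, clim, cp, bp = burden_params(),
                             years = NULL, mode = c("fixed", "sensitivity"),
                             prevalence_increase = 0.3,
                             ramp_from = 2023L, ramp_to = 2050L,
                             envelope = TRUE) {
  mode <- match.arg(mode)
  scenario <- validate_daily_series(scenario)
  yr_all <- as.integer(format(scenario$date, "%Y"))
  counts <- table(yr_all)
  complete_years <- as.integer(names(counts)[counts >= 365])
  years <- years %||% complete_years
  missing_years <- setdiff(years, complete_years)
  stop_if(length(missing_years) > 0,
          sprintf("scenario does not fully cover year(s) %s",
                  paste(missing_years, collapse = ", ")))
  if (mode == "sensitivity") {
    stop_if(is.null(cp$pop_forecast),
            "sensitivity mode requires cp$pop_forecast (year, apop)")
  }
  rows <- vector("list", length(years))
  for (k in seq_along(years)) {
    y <- years[k]
    ex <- daily_excess_risk(curve, scenario, clim, year = y)
    exl <- exu <- NULL
    if (envelope) {
      exl <- excess_at_envelope(curve, scenario, clim, y, "lower")
      exu <- excess_at_envelope(curve, scenario, clim, y, "upper")
    }
    cp_y <- cp
    if (mode == "sensitivity") {
      frac <- min(1, max(0, (y - ramp_from) / (ramp_to - ramp_from)))
      cp_y$p0 <- min(1, cp$p0 * (1 + prevalence_increase * frac))
      i <- match(y, cp$pop_forecast$year)
      if (!is.na(i)) cp_y$apop <- cp$pop_forecast$apop[i]
    }
    rows[[k]] <- burden_for_year(ex, cp_y, bp, excess_lower = exl,
                                 excess_upper = exu)
  }
  out <- do.call(rbind, rows)
  cum_cols <- c("person_days", "yll_mean", "yld_mean", "daly_mean",
                "cost_mean", "presenteeism_mean", "absenteeism_mean",
                "labor_loss_mean")
  attr(out, "cumulative") <- colSums(out[, cum_cols, drop = FALSE])
  attr(out, "mode") <- mode
  class(out) <- c("scenario_trajectory", "data.frame")
  out
}
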