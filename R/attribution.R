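#' Day-of-year temperature climatology
#'
#' The counterfactual baseline for warming attribution: the mean temperature
#' for each of 365 days of the year over a historical window (1950-1990 by
#' default). Feb 29 is dropped before averaging so every year contributes
#' exactly 365 day slots.
#'
#' @param series A `daily_series` covering at least one full year inside the
#'   window.
#' @param window Length-2 integer years (inclusive).
#' @return An object of class `climatology`: numeric length-365 vector of
#'   day-of-year means, with attributes `window`, `n_years`, `country`.
#' @export
climatology_1950_1990 <- function(series, window = c(1950L, 1990L)) {
  series <- validate_daily_series(series)
  yr <- as.integer(format(series$date, "%Y"))
  in_win <- yr >= window[1] & yr <= window[2]
  stop_if(!any(in_win), "series has no coverage inside the climatology window")
  d <- series$date[in_win]
  t <- series$tmean[in_win]
  doy <- doy365(d)
  keep <- !is.na(doy)   # drop Feb 29
  means <- as.numeric(tapply(t[keep], doy[keep], mean))
  got <- sort(unique(doy[keep]))
  stop_if(length(got) != 365L || !identical(got, 1:365),
          "window coverage must include every day of year")
  structure(means, window = window,
            n_years = length(unique(yr[in_win])),
            country = attr(series, "country"),
            class = "climatology")
}

#' Daily excess OSA risk relative to the historical climatology
#'
#' For each of the 365 days of one calendar year, evaluates
#' `RR(T_d) - RR(Thist_d)` on the risk-ratio scale through the cumulative
#' exposure-response curve, where `Thist` is the 1950-1990 day-of-year
#' climatology. Temperatures outside the curve grid are clipped to the grid
#' ends (flat extrapolation) and counted.
#'
#' @param curve An `exposure_response_curve`.
#' @param year_series A `daily_series` covering one full calendar year (or
#'   containing it; use `year` to select).
#' @param clim A [climatology_1950_1990()] result.
#' @param year Calendar year to extract; default the first complete year in
#'   `year_series`.
#' @param clip Clip out-of-grid temperatures to the grid ends.
#' @return An object of class `excess_series`: list with `year`, `values`
#'   (365 daily excess RR differences), `sum`, `mean`, `n_clipped`.
#' @export
daily_excess_risk <- function(curve, year_series, clim, year = NULL,
                              clip = TRUE) {
  stopifnot(inherits(clim, "climatology"), length(clim) == 365L)
  year_series <- validate_daily_series(year_series)
  yrs <- as.integer(format(year_series$date, "%Y"))
  year <- year %||% yrs[1]
  sel <- yrs == year
  d <- year_series$date[sel]
  t <- year_series$tmean[sel]
  doy <- doy365(d)
  keep <- !is.na(doy)
  stop_if(sum(keep) < 365L,
          sprintf("year %d has %d usable days; 365 required", year, sum(keep)))
  t365 <- numeric(365L)
  t365[doy[keep]] <- t[keep]

  rr_now <- curve_log_rr(curve, t365, clip = clip)
  rr_hist <- curve_log_rr(curve, as.numeric(clim), clip = clip)
  values <- exp(rr_now$log_rr) - exp(rr_hist$log_rr)
  structure(list(year = year, values = values, sum = sum(values),
                 mean = mean(values),
                 n_clipped = rr_now$n_clipped + rr_hist$n_clipped),
            class = "excess_series")
}

#' Excess OSA person-days
#'
#' Converts a year's daily excess risk into additional person-days with OSA:
#' `sum over days of excess_d * p0 * APOP`, where `p0` is the country OSA
#' prevalence and `APOP` its adult population.
#'
#' @param excess An `excess_series`.
#' @param p0 OSA prevalence (fraction in `[0, 1]`).
#' @param apop Adult population (persons, >= 0).
#' @return Excess person-days (numeric scalar).
#' @export
excess_person_days <- function(excess, p0, apop) {
  stopifnot(inherits(excess, "excess_series"))
  assert_prob(p0, "p0")
  stop_if(apop < 0, "'apop' must be >= 0")
  excess$sum * p0 * apop
}
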