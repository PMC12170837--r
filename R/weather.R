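#' Weather generator configuration
#'
#' Describes a synthetic daily temperature series for one country: an annual
#' mean, a sinusoidal seasonal cycle, stationary AR(1) day-to-day noise, and
#' an optional linear warming trend. The defaults emulate a temperate
#' mid-latitude climate whose empirical 25th/99th temperature percentiles sit
#' near 6.4 and 27.3 degrees C, the contrast at which exposure-response
#' summaries are reported.
#'
#' @param label Country label.
#' @param mean_temp Annual mean temperature (degrees C).
#' @param seasonal_amplitude Amplitude of the seasonal sinusoid (degrees C,
#'   >= 0); the cycle peaks on day-of-year 197 (mid July).
#' @param noise_sd Stationary standard deviation of the AR(1) day-to-day
#'   noise (degrees C, >= 0).
#' @param noise_ar AR(1) autocorrelation, in `[0, 1)`.
#' @param trend_per_decade Linear warming trend (degrees C per decade).
#' @param start_year,end_year First and last calendar year generated
#'   (inclusive); `end_year >= start_year`.
#' @param diurnal_half_range Half-range used to derive daily minimum and
#'   maximum from the mean (degrees C); fixed at 4 by default.
#' @param covariates Logical; also generate the standard meteorological
#'   covariates (cloud cover fraction, relative humidity, surface pressure,
#'   precipitation, wind speed, fine particulate matter).
#' @param seed Integer seed; identical configurations yield identical series.
#' @return An object of class `weather_config`.
#' @export
weather_config <- function(label = "synthland",
                           mean_temp = 12.5,
                           seasonal_amplitude = 9.2,
                           noise_sd = 3.6,
                           noise_ar = 0.6,
                           trend_per_decade = 0,
                           start_year = 2022,
                           end_year = 2023,
                           diurnal_half_range = 4,
                           covariates = FALSE,
                           seed = 1L) {
  assert_finite(mean_temp, "mean_temp")
  assert_finite(seasonal_amplitude, "seasonal_amplitude")
  assert_finite(noise_sd, "noise_sd")
  assert_finite(trend_per_decade, "trend_per_decade")
  stop_if(seasonal_amplitude < 0, "'seasonal_amplitude' must be >= 0")
  stop_if(noise_sd < 0, "'noise_sd' must be >= 0")
  stop_if(!is.finite(noise_ar) || noise_ar < 0 || noise_ar >= 1,
          "'noise_ar' must be in [0, 1)")
  stop_if(end_year < start_year, "'end_year' must be >= 'start_year'")
  structure(
    list(label = label, mean_temp = mean_temp,
         seasonal_amplitude = seasonal_amplitude, noise_sd = noise_sd,
         noise_ar = noise_ar, trend_per_decade = trend_per_decade,
         start_year = as.integer(start_year), end_year = as.integer(end_year),
         diurnal_half_range = diurnal_half_range,
         covariates = isTRUE(covariates), seed = as_seed(seed)),
    class = "weather_config"
  )
}

#' Simulate a daily temperature series for one country
#'
#' Daily mean temperature is the sum of the annual mean, a seasonal sinusoid
#' peaking in mid July, stationary AR(1) noise, and a linear trend in years
#' since the series start. Daily minimum/maximum are the mean minus/plus a
#' fixed diurnal half-range. Feb 29 rows are generated but flagged so that
#' downstream day-of-year climatologies can drop them.
#'
#' @param cfg A [weather_config()].
#' @return A `data.frame` of class `daily_series` with columns `date`,
#'   `tmean`, `tmin`, `tmax`, `leap` and, when requested, the meteorological
#'   covariates. The country label and the seed are kept as attributes.
#' @export
simulate_country_weather <- function(cfg) {
  stopifnot(inherits(cfg, "weather_config"))
  dates <- seq(as.Date(sprintf("%d-01-01", cfg$start_year)),
               as.Date(sprintf("%d-12-31", cfg$end_year)), by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- cfg$seasonal_amplitude * cos(2 * pi * (doy - 197) / 365.25)
  yrs <- as.numeric(dates - dates[1]) / 365.25
  trend <- cfg$trend_per_decade * yrs / 10

  out <- with_seed(cfg$seed, {
    e <- numeric(n)
    if (cfg$noise_sd > 0) {
      z <- stats::rnorm(n)
      e[1] <- cfg$noise_sd * z[1]
      innov_sd <- cfg$noise_sd * sqrt(1 - cfg$noise_ar^2)
      for (i in seq_len(n)[-1]) {
        e[i] <- cfg$noise_ar * e[i - 1] + innov_sd * z[i]
      }
    }
    df <- data.frame(
      date = dates,
      tmean = cfg$mean_temp + seasonal + e + trend
    )
    if (cfg$covariates) {
      ar1 <- function(sd, rho) {
        u <- numeric(n)
        zz <- stats::rnorm(n)
        u[1] <- sd * zz[1]
        for (i in seq_len(n)[-1]) u[i] <- rho * u[i - 1] + sd * sqrt(1 - rho^2) * zz[i]
        u
      }
      df$cloud_cover <- stats::plogis(0.2 + ar1(1, 0.5))
      df$rel_humidity <- pmin(100, pmax(5, 70 - 0.8 * seasonal + ar1(8, 0.5)))
      df$pressure <- 1013 + ar1(6, 0.7)
      df$precipitation <- pmax(0, ar1(3, 0.3))
      df$wind_speed <- pmax(0, 4 + ar1(1.5, 0.4))
      df$pm25 <- pmax(0.5, 12 + ar1(4, 0.6))
    }
    df
  })
  out$tmin <- out$tmean - cfg$diurnal_half_range
  out$tmax <- out$tmean + cfg$diurnal_half_range
  out$leap <- format(dates, "%m-%d") == "02-29"
  attr(out, "country") <- cfg$label
  attr(out, "seed") <- cfg$seed
  class(out) <- c("daily_series", "data.frame")
  validate_daily_series(out)
}

#' Validate a daily temperature series
#'
#' Checks the invariants of the daily-series container: strictly increasing
#' contiguous dates and `tmin <= tmean <= tmax` wherever all three are
#' present.
#'
#' @param series A `data.frame` with at least `date` and `tmean`.
#' @return The series, invisibly classed as `daily_series`.
#' @export
validate_daily_series <- function(series) {
  stop_if(!all(c("date", "tmean") %in% names(series)),
          "daily series needs columns 'date' and 'tmean'")
  d <- as.Date(series$date)
  stop_if(any(is.na(d)), "unparseable dates in daily series")
  dd <- diff(as.integer(d))
  stop_if(any(dd <= 0), "dates must be strictly increasing")
  stop_if(any(dd != 1), "dates must be contiguous (no gaps)")
  if (all(c("tmin", "tmax") %in% names(series))) {
    ok <- stats::complete.cases(series[, c("tmin", "tmean", "tmax")])
    stop_if(any(series$tmin[ok] > series$tmean[ok]) ||
              any(series$tmean[ok] > series$tmax[ok]),
            "need tmin <= tmean <= tmax")
  }
  series$date <- d
  if (!inherits(series, "daily_series")) {
    class(series) <- c("daily_series", class(series))
  }
  invisible(series)
}
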