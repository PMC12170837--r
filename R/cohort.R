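#' Synthetic cohort configuration
#'
#' Describes the generative model for a nightly OSA panel. The nightly
#' indicator is Bernoulli with a log-linear probability model:
#' `log p = log(p0) + user intercept + seasonal term + day-of-week term +
#' sum over lags of lag_effect[l] * g(T[d - l]) + covariate terms`,
#' where `g` is a scalar exposure transform built from the same natural
#' cubic spline basis used by the fitter (coefficients `shape_coef` on the
#' centered basis), so the generative cumulative risk ratio between any two
#' temperatures is available in closed form and the fitted model is
#' correctly specified. The log link (rather than logit) makes the
#' generative contrast a risk ratio, the estimand of the conditional Poisson
#' fit. A piecewise-linear transform (`truth = "piecewise"`) is provided as
#' a deliberately mis-specified truth for robustness checks.
#'
#' Defaults follow the study conditions: baseline nightly probability 0.254
#' for OSA (apnea-hypopnea index >= 15) and 0.089 for severe OSA (>= 30),
#' nightly total sleep time Normal(7.4, 0.8) hours, and a 4-day lag window.
#'
#' @param n_users Number of users.
#' @param nights_per_user Nights per user (contiguous, all users aligned on
#'   the same dates).
#' @param start_date First night (Date or string).
#' @param baseline_prob Baseline nightly OSA probability at the reference
#'   temperature, in (0, 1).
#' @param baseline_prob_severe Baseline nightly severe-OSA probability.
#' @param user_sd Standard deviation of the user-level random intercept on
#'   the log scale (the mean is shifted by `-user_sd^2/2` so the marginal
#'   baseline probability stays at `baseline_prob`).
#' @param seasonal_amplitude Amplitude (log scale) of the seasonal trend;
#'   internally projected onto the 4-df day-of-year spline so the fitted
#'   model spans the truth.
#' @param dow_effects Length-6 log-scale effects for ISO weekdays 2..7
#'   (Monday is the reference level).
#' @param max_lag Maximum exposure lag in days.
#' @param lag_effects,lag_effects_severe Length `max_lag + 1` vectors of
#'   per-lag coefficients multiplying `g(T)`; usually set via
#'   [calibrate_lag_effects()].
#' @param covariate_effects Named numeric vector of linear (log-scale)
#'   effects for weather covariates present in the series.
#' @param tst_mean,tst_sd Nightly total-sleep-time distribution (hours).
#' @param exposure_spec Frozen [spline_spec()] for the exposure transform
#'   (shared with the fitter); typically from [spline_spec_from_data()] on
#'   the weather series.
#' @param shape_coef Coefficients of the exposure transform on the centered
#'   exposure basis; `NULL` uses a smooth monotone default (softplus-like
#'   rise above ~15 degrees C projected onto the basis).
#' @param truth `"spline"` (default, shared code path with the fitter) or
#'   `"piecewise"` (hinge transform `max(T - piecewise_break, 0)`).
#' @param piecewise_break Hinge location for the piecewise truth.
#' @param seed Integer seed. Per-user substreams are split deterministically
#'   so enlarging the cohort never perturbs existing users.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_users = 2000L,
                          nights_per_user = 365L,
                          start_date = "2023-01-01",
                          baseline_prob = 0.254,
                          baseline_prob_severe = 0.089,
                          user_sd = 0.3,
                          seasonal_amplitude = 0.08,
                          dow_effects = c(0, 0, 0, 0.01, 0.03, 0.02),
                          max_lag = 4L,
                          lag_effects = NULL,
                          lag_effects_severe = NULL,
                          covariate_effects = NULL,
                          tst_mean = 7.4,
                          tst_sd = 0.8,
                          exposure_spec = NULL,
                          shape_coef = NULL,
                          truth = c("spline", "piecewise"),
                          piecewise_break = 15,
                          seed = 1L) {
  assert_prob(baseline_prob, "baseline_prob")
  assert_prob(baseline_prob_severe, "baseline_prob_severe")
  stop_if(baseline_prob <= 0 || baseline_prob >= 1,
          "'baseline_prob' must be in (0, 1)")
  stop_if(user_sd < 0, "'user_sd' must be >= 0")
  stop_if(length(dow_effects) != 6L, "'dow_effects' must have length 6")
  max_lag <- as.integer(max_lag)
  nlag <- max_lag + 1L
  lag_effects <- lag_effects %||% numeric(nlag)
  lag_effects_severe <- lag_effects_severe %||% numeric(nlag)
  stop_if(length(lag_effects) != nlag || length(lag_effects_severe) != nlag,
          "lag-effect vectors must have length max_lag + 1")
  truth <- match.arg(truth)
  structure(
    list(n_users = as.integer(n_users),
         nights_per_user = as.integer(nights_per_user),
         start_date = as.Date(start_date),
         baseline_prob = baseline_prob,
         baseline_prob_severe = baseline_prob_severe,
         user_sd = user_sd,
         seasonal_amplitude = seasonal_amplitude,
         dow_effects = dow_effects,
         max_lag = max_lag,
         lag_effects = lag_effects,
         lag_effects_severe = lag_effects_severe,
         covariate_effects = covariate_effects,
         tst_mean = tst_mean, tst_sd = tst_sd,
         exposure_spec = exposure_spec,
         shape_coef = shape_coef,
         truth = truth, piecewise_break = piecewise_break,
         seed = as_seed(seed)),
    class = "cohort_config"
  )
}

# Default exposure-transform shape: smooth monotone rise above ~15 C,
# projected onto the (centered) exposure basis so the truth lies exactly in
# the fitted spline space.
default_shape_coef <- function(exposure_spec) {
  grid <- seq(exposure_spec$boundary[1], exposure_spec$boundary[2],
              length.out = 200)
  target <- 4 * log1p(exp((grid - 15) / 4))
  b <- natural_spline_basis(grid, exposure_spec)
  as.numeric(stats::coef(stats::lm.fit(unclass(b), target)))
}

# Resolve spec-dependent config fields against a weather series.
resolve_cohort_config <- function(cfg, weather) {
  if (is.null(cfg$exposure_spec) || is.null(cfg$exposure_spec$knots)) {
    cfg$exposure_spec <- spline_spec_from_data(weather$tmean, df = 4L)
  }
  if (is.null(cfg$shape_coef) && cfg$truth == "spline") {
    cfg$shape_coef <- default_shape_coef(cfg$exposure_spec)
  }
  cfg
}

#' Scalar exposure transform of the generative model
#'
#' @param cfg A resolved [cohort_config()] (exposure spec frozen).
#' @param t Temperatures (degrees C).
#' @return `g(t)`, the scalar transform multiplied by the per-lag effects.
#' @export
exposure_transform <- function(cfg, t) {
  if (cfg$truth == "piecewise") return(pmax(t - cfg$piecewise_break, 0))
  stop_if(is.null(cfg$exposure_spec) || is.null(cfg$exposure_spec$knots) ||
            is.null(cfg$shape_coef),
          "config not resolved: freeze it with a weather series first")
  drop(unclass(natural_spline_basis(t, cfg$exposure_spec)) %*% cfg$shape_coef)
}

#' Closed-form generative cumulative risk ratio
#'
#' The generative cumulative risk ratio between two temperatures, implied by
#' the configuration: `exp(sum(lag_effects) * (g(t_high) - g(t_low)))`.
#' This is the quantity the case-time-series estimator should recover.
#'
#' @param cfg A resolved [cohort_config()].
#' @param t_high,t_low Temperatures contrasted (degrees C).
#' @param outcome `"osa"` or `"severe"`.
#' @return Risk ratio (positive scalar).
#' @export
generative_cumulative_rr <- function(cfg, t_high, t_low,
                                     outcome = c("osa", "severe")) {
  outcome <- match.arg(outcome)
  th <- if (outcome == "osa") cfg$lag_effects else cfg$lag_effects_severe
  exp(sum(th) * (exposure_transform(cfg, t_high) - exposure_transform(cfg, t_low)))
}

#' Calibrate per-lag effects to a target cumulative risk ratio
#'
#' Rescales the lag-effect vector (keeping the relative lag shares) so the
#' generative cumulative risk ratio at the stated temperature contrast
#' equals `target_rr` exactly.
#'
#' @param cfg A [cohort_config()]; resolved against `weather` if supplied.
#' @param target_rr Target cumulative risk ratio.
#' @param t_high,t_low Contrast temperatures; defaults are the study's
#'   99th/25th percentile contrast (27.3 vs 6.4 degrees C).
#' @param outcome `"osa"` or `"severe"`.
#' @param lag_share Relative contribution of each lag (length `max_lag + 1`,
#'   normalised internally); default is a declining profile.
#' @param weather Optional daily series used to resolve the exposure spec.
#' @return The config with the calibrated lag-effect vector.
#' @export
calibrate_lag_effects <- function(cfg, target_rr, t_high = 27.3, t_low = 6.4,
                                  outcome = c("osa", "severe"),
                                  lag_share = NULL, weather = NULL) {
  outcome <- match.arg(outcome)
  stop_if(target_rr <= 0, "'target_rr' must be positive")
  if (!is.null(weather)) cfg <- resolve_cohort_config(cfg, weather)
  nlag <- cfg$max_lag + 1L
  share <- lag_share %||% rev(seq_len(nlag))^1.5
  stop_if(length(share) != nlag, "'lag_share' must have length max_lag + 1")
  share <- share / sum(share)
  dg <- exposure_transform(cfg, t_high) - exposure_transform(cfg, t_low)
  stop_if(abs(dg) < 1e-12, "transform does not separate the two temperatures")
  eff <- share * log(target_rr) / dg
  if (outcome == "osa") cfg$lag_effects <- eff else cfg$lag_effects_severe <- eff
  cfg
}

#' Simulate a nightly OSA panel
#'
#' Draws one row per user-night with nightly OSA and severe-OSA indicators,
#' total sleep time, the exposure and its lags, and any weather covariates.
#' All users share the same calendar nights (weather is common to the
#' country); user-level heterogeneity enters through log-scale random
#' intercepts drawn from per-user substreams. Nightly probabilities are
#' capped at 0.995 (cap hits are counted in attribute `"n_capped"`).
#'
#' @param weather A `daily_series` covering all cohort nights plus the
#'   `max_lag` preceding days.
#' @param cfg A [cohort_config()].
#' @return A `data.frame` of class `nightly_panel` with columns `user`,
#'   `date`, `osa`, `osa_severe`, `tst`, `tmean`, `tlag1..tlag<max_lag>`,
#'   covariates, and `miss_ahi`. The resolved config and the frozen
#'   exposure/day-of-year spline specs are attached as attributes.
#' @export
simulate_cohort <- function(weather, cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  weather <- validate_daily_series(weather)
  cfg <- resolve_cohort_config(cfg, weather)
  nights <- seq(cfg$start_date, by = "day", length.out = cfg$nights_per_user)
  need <- seq(cfg$start_date - cfg$max_lag, max(nights), by = "day")
  stop_if(!all(need %in% weather$date),
          "weather must cover all cohort dates plus max_lag preceding days")

  widx <- match(nights, weather$date)
  lagT <- sapply(0:cfg$max_lag, function(l) weather$tmean[widx - l])
  gmat <- matrix(exposure_transform(cfg, as.numeric(lagT)), nrow = length(nights))
  temp_term <- drop(gmat %*% cfg$lag_effects)
  temp_term_sev <- drop(gmat %*% cfg$lag_effects_severe)

  doy <- as.integer(format(nights, "%j"))
  doy_spec <- spline_spec_from_data(rep(doy, 2L), df = 4L,
                                    center = stats::median(doy))
  doy_basis <- unclass(natural_spline_basis(doy, doy_spec))
  seas_coef <- as.numeric(stats::coef(stats::lm.fit(
    doy_basis, cfg$seasonal_amplitude * cos(2 * pi * (doy - 197) / 365.25))))
  seas <- drop(doy_basis %*% seas_coef)

  wday <- as.integer(format(nights, "%u"))
  dow <- c(0, cfg$dow_effects)[wday]

  cov_term <- 0
  cov_cols <- character()
  if (!is.null(cfg$covariate_effects)) {
    cov_cols <- intersect(names(cfg$covariate_effects), names(weather))
    for (cc in cov_cols) {
      x <- weather[[cc]][widx]
      cov_term <- cov_term + cfg$covariate_effects[[cc]] * (x - mean(x))
    }
  }

  eta_shared <- seas + dow + cov_term
  n_nights <- length(nights)
  users <- seq_len(cfg$n_users)
  osa <- osa_sev <- integer(cfg$n_users * n_nights)
  tst <- numeric(cfg$n_users * n_nights)
  n_capped <- 0L
  base <- log(cfg$baseline_prob) - cfg$user_sd^2 / 2
  base_sev <- log(cfg$baseline_prob_severe) - cfg$user_sd^2 / 2
  for (u in users) {
    rows <- (u - 1L) * n_nights + seq_len(n_nights)
    with_seed(unit_seed(cfg$seed, u), {
      a <- stats::rnorm(2L, 0, cfg$user_sd)
      tst[rows] <- stats::rnorm(n_nights, cfg$tst_mean, cfg$tst_sd)
      p <- exp(base + a[1] + eta_shared + temp_term)
      p_sev <- exp(base_sev + a[2] + eta_shared + temp_term_sev)
      n_capped <- n_capped + sum(p > 0.995) + sum(p_sev > 0.995)
      osa[rows] <- stats::rbinom(n_nights, 1L, pmin(p, 0.995))
      osa_sev[rows] <- stats::rbinom(n_nights, 1L, pmin(p_sev, 0.995))
    })
  }

  panel <- data.frame(
    user = rep(users, each = n_nights),
    date = rep(nights, cfg$n_users),
    osa = osa, osa_severe = osa_sev,
    tst = tst,
    tmean = rep(weather$tmean[widx], cfg$n_users)
  )
  # daily extremes (when present) support the min/max-exposure sensitivity fits
  if ("tmin" %in% names(weather)) panel$tmin <- rep(weather$tmin[widx], cfg$n_users)
  if ("tmax" %in% names(weather)) panel$tmax <- rep(weather$tmax[widx], cfg$n_users)
  if (cfg$max_lag > 0) {
    for (l in seq_len(cfg$max_lag)) {
      panel[[paste0("tlag", l)]] <- rep(lagT[, l + 1L], cfg$n_users)
    }
  }
  for (cc in cov_cols) panel[[cc]] <- rep(weather[[cc]][widx], cfg$n_users)
  panel$miss_ahi <- FALSE
  attr(panel, "config") <- cfg
  attr(panel, "exposure_spec") <- cfg$exposure_spec
  attr(panel, "doy_spec") <- doy_spec
  attr(panel, "n_capped") <- n_capped
  attr(panel, "seed") <- cfg$seed
  class(panel) <- c("nightly_panel", "data.frame")
  panel
}

#' Apply the short-sleep missingness rule
#'
#' The apnea-hypopnea index cannot be computed on nights with less than five
#' hours of sleep, so both nightly indicators are set to missing wherever
#' total sleep time falls below 5 h. With `temperature_dependent = TRUE`,
#' total sleep time is first shifted downward on hot days (emulating the
#' heat/short-sleep association), which makes missingness informative and
#' lets the missingness-bias sensitivity analysis be exercised; the slope of
#' that shift is a free simulation parameter, not an estimate.
#'
#' @param panel A `nightly_panel`.
#' @param temperature_dependent Shift sleep downward on hot days first.
#' @param slope Hours of sleep lost per degree above `threshold`.
#' @param threshold Temperature (degrees C) above which sleep is shortened.
#' @return The panel with updated `tst`, `miss_ahi`, and indicators.
#' @export
apply_missingness <- function(panel, temperature_dependent = FALSE,
                              slope = 0.1, threshold = 25) {
  stop_if(!"tst" %in% names(panel), "panel has no total-sleep-time column")
  if (temperature_dependent) {
    panel$tst <- panel$tst - slope * pmax(panel$tmean - threshold, 0)
  }
  miss <- panel$tst < 5
  panel$miss_ahi <- miss
  panel$osa[miss] <- NA_integer_
  panel$osa_severe[miss] <- NA_integer_
  panel
}
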