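# Independent oracles used across the suite. These reimplement textbook
# algorithms from first principles so agreement with the package is a real
# cross-check, not a shared code path.

# Natural cubic spline interpolation through (x, y) via the classic
# tridiagonal system for the interior second derivatives (M_1 = M_n = 0).
# Returns a function evaluating the interpolant.
tridiag_natural_spline <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  # tridiagonal system A m = r for interior second derivatives
  ni <- n - 2L
  A <- matrix(0, ni, ni)
  r <- numeric(ni)
  for (i in seq_len(ni)) {
    A[i, i] <- 2 * (h[i] + h[i + 1])
    if (i > 1) A[i, i - 1] <- h[i]
    if (i < ni) A[i, i + 1] <- h[i + 1]
    r[i] <- 6 * ((y[i + 2] - y[i + 1]) / h[i + 1] - (y[i + 1] - y[i]) / h[i])
  }
  m <- c(0, solve(A, r), 0)
  function(t) {
    vapply(t, function(tt) {
      i <- findInterval(tt, x, rightmost.closed = TRUE)
      i <- min(max(i, 1L), n - 1L)
      dx1 <- tt - x[i]; dx2 <- x[i + 1] - tt
      (m[i] * dx2^3 + m[i + 1] * dx1^3) / (6 * h[i]) +
        (y[i] / h[i] - m[i] * h[i] / 6) * dx2 +
        (y[i + 1] / h[i] - m[i + 1] * h[i] / 6) * dx1
    }, numeric(1))
  }
}

# Naive double-loop cross-basis: element-by-element evaluation of exposure
# basis function j at the lag-l exposure, centered at the reference.
naive_cross_basis <- function(lagged, spec) {
  es <- spec$exposure_spec
  nlag <- spec$max_lag + 1L
  out <- matrix(NA_real_, nrow(lagged), es$df * nlag)
  for (i in seq_len(nrow(lagged))) {
    for (l in 0:spec$max_lag) {
      bi <- unclass(natural_spline_basis(lagged[i, l + 1L], es))
      for (j in seq_len(es$df)) {
        out[i, l * es$df + j] <- bi[1, j]
      }
    }
  }
  out
}

# Small synthetic panel for fitter tests: a handful of users over a few
# months, with an optional true exposure effect on the log-probability scale.
make_small_panel <- function(n_users = 8, nights = 90, seed = 42,
                             target_rr = NULL, start_year = 2023) {
  w <- simulate_country_weather(weather_config(
    start_year = start_year - 1L, end_year = start_year, seed = seed))
  cfg <- cohort_config(n_users = n_users, nights_per_user = nights,
                       start_date = sprintf("%d-01-10", start_year),
                       seed = seed)
  if (!is.null(target_rr)) {
    cfg <- calibrate_lag_effects(cfg, target_rr, weather = w)
  } else {
    cfg <- resolve_cohort_config(cfg, w)
  }
  list(weather = w, cfg = cfg, panel = simulate_cohort(w, cfg))
}

# resolve_cohort_config is internal; re-export for helpers
resolve_cohort_config <- osaheat:::resolve_cohort_config

# Flat exposure-response curve builder for attribution tests: a grid-only
# curve with prescribed log-RR values.
toy_curve <- function(temp, log_rr, var = 0, ref = temp[1]) {
  structure(data.frame(temp = temp, log_rr = log_rr, var = var),
            reference = ref, provenance = "external",
            class = c("exposure_response_curve", "data.frame"))
}

# Constant daily series spanning the given years.
constant_series <- function(value, start_year, end_year) {
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", end_year)), by = "day")
  validate_daily_series(data.frame(date = dates, tmean = value))
}

# Reference country/burden parameters used by several tests.
test_country <- function(...) {
  args <- list(label = "testland", p0 = 0.25, apop = 1e7,
               mva_death_rate = 2e-7, rle = 30, labor_force = 5e6,
               pt_share = 0.2, gdp_pc = 5e4, gdp_pc_employed = 1e5)
  args[names(list(...))] <- list(...)
  do.call(country_params, args)
}
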