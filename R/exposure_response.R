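#' Cumulative exposure-response curve
#'
#' Summarises a case-time-series fit by summing the lag-specific effects
#' over the lag window: at each grid temperature `t`, the cumulative log-RR
#' is `sum over lags l and basis functions j of beta[j,l] * (b_j(t) -
#' b_j(ref))`. With the indicator lag basis this is `d(t)' B` where `d(t)`
#' is the centered exposure basis row and `B` the lag-summed coefficient
#' vector; its variance is the quadratic form with the lag-summed
#' covariance, which the curve stores so any later contrast is exact.
#'
#' @param fit A `ctseries_fit` from [fit_ctseries()] (or one carrying
#'   `cb_spec` and `cb_cols`).
#' @param grid Temperatures at which to evaluate the curve; default 100
#'   points spanning the exposure boundary knots.
#' @param allow_extrapolation Permit grid values beyond the boundary knots
#'   (the natural spline is linear there); refused by default.
#' @return An object of class `exposure_response_curve`: a `data.frame`
#'   (`temp`, `log_rr`, `var`) plus attributes `reference`, `coef`
#'   (lag-summed), `vcov` (lag-summed), `spec`, `p0_ref`, `provenance`.
#' @export
cumulative_curve <- function(fit, grid = NULL, allow_extrapolation = FALSE) {
  stop_if(is.null(fit$cb_spec) || is.null(fit$cb_cols),
          "fit carries no cross-basis bookkeeping")
  es <- fit$cb_spec$exposure_spec
  nlag <- fit$cb_spec$max_lag + 1L
  df <- es$df
  stop_if(length(fit$cb_cols) != df * nlag,
          "cross-basis bookkeeping does not match the spec")
  grid <- grid %||% seq(es$boundary[1], es$boundary[2], length.out = 100L)
  stop_if(is.unsorted(grid, strictly = TRUE), "grid must be strictly increasing")
  if (!allow_extrapolation) {
    stop_if(any(grid < es$boundary[1] - 1e-9) || any(grid > es$boundary[2] + 1e-9),
            "grid outside the boundary-knot range; set allow_extrapolation = TRUE")
  }
  # lag-summing matrix: column order is b1..bdf within lag0, then lag1, ...
  A <- do.call(cbind, replicate(nlag, diag(df), simplify = FALSE))
  beta_cb <- fit$coef[fit$cb_cols]
  V_cb <- fit$vcov[fit$cb_cols, fit$cb_cols, drop = FALSE]
  B <- drop(A %*% beta_cb)
  V <- A %*% V_cb %*% t(A)

  D <- unclass(natural_spline_basis(grid, es))  # centered at the reference
  log_rr <- drop(D %*% B)
  v <- rowSums((D %*% V) * D)
  out <- data.frame(temp = grid, log_rr = log_rr, var = pmax(v, 0))
  structure(out,
            reference = es$center, coef = B, vcov = V, spec = es,
            p0_ref = fit$p0_ref %||% NA_real_,
            provenance = "ctseries_fit",
            class = c("exposure_response_curve", "data.frame"))
}

# Evaluate cumulative log-RR (and variance) at arbitrary temperatures.
# Exact when the curve carries its basis coefficients; linear interpolation
# on the stored grid otherwise. Out-of-range temperatures are clipped to the
# grid ends (flat extrapolation) when clip = TRUE.
curve_log_rr <- function(curve, t, clip = FALSE) {
  rng <- range(curve$temp)
  clipped <- t < rng[1] | t > rng[2]
  stop_if(!clip && any(clipped),
          "temperature outside the curve grid (extrapolation refused)")
  t <- pmin(pmax(t, rng[1]), rng[2])
  if (!is.null(attr(curve, "coef"))) {
    D <- unclass(natural_spline_basis(t, attr(curve, "spec")))
    V <- attr(curve, "vcov")
    list(log_rr = drop(D %*% attr(curve, "coef")),
         var = pmax(rowSums((D %*% V) * D), 0),
         exact = TRUE, n_clipped = sum(clipped))
  } else {
    list(log_rr = stats::approx(curve$temp, curve$log_rr, xout = t)$y,
         var = pmax(stats::approx(curve$temp, curve$var, xout = t)$y, 0),
         exact = FALSE, n_clipped = sum(clipped))
  }
}

#' Risk-ratio contrast between two temperatures
#'
#' `RR = exp(logRR(t_high) - logRR(t_low))` with a delta-method 95% CI on
#' the log scale (z = 1.959964). When the curve carries its basis
#' coefficients (a fitted curve) the variance of the difference contrast is
#' exact; for an external grid-only curve the variance is exact when
#' `t_low` is the curve's reference and otherwise conservatively taken as
#' the sum of the two pointwise variances (covariance unavailable).
#'
#' @param curve An `exposure_response_curve`.
#' @param t_high,t_low Temperatures contrasted (within the grid).
#' @return A list of class `rr_contrast`: `rr`, `ci` (length 2), `t_high`,
#'   `t_low`.
#' @export
rr_contrast <- function(curve, t_high, t_low) {
  z <- 1.959964
  rng <- range(curve$temp)
  stop_if(t_high < rng[1] || t_high > rng[2] || t_low < rng[1] || t_low > rng[2],
          "temperature outside the curve grid (extrapolation refused)")
  if (!is.null(attr(curve, "coef"))) {
    es <- attr(curve, "spec")
    d <- unclass(natural_spline_basis(t_high, es)) -
      unclass(natural_spline_basis(t_low, es))
    log_rr <- drop(d %*% attr(curve, "coef"))
    v <- drop(d %*% attr(curve, "vcov") %*% t(d))
  } else {
    hi <- curve_log_rr(curve, t_high)
    lo <- curve_log_rr(curve, t_low)
    log_rr <- hi$log_rr - lo$log_rr
    ref <- attr(curve, "reference")
    v <- if (!is.null(ref) && isTRUE(all.equal(t_low, ref))) {
      hi$var
    } else {
      hi$var + lo$var
    }
  }
  se <- sqrt(max(v, 0))
  structure(list(rr = exp(log_rr),
                 ci = exp(log_rr + c(-1, 1) * z * se),
                 t_high = t_high, t_low = t_low),
            class = "rr_contrast")
}

#' @export
print.rr_contrast <- function(x, ...) {
  cat(sprintf("RR(%.1f vs %.1f C) = %.3f [%.3f, %.3f]\n",
              x$t_high, x$t_low, x$rr, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Convert an odds ratio to a risk ratio
#'
#' The Zhang-Yu conversion `RR = OR / (1 - p0 + p0 * OR)`, where `p0` is the
#' outcome risk in the reference (unexposed) group; applied element-wise so
#' point estimates and CI bounds convert together.
#'
#' @param or_value Odds ratio(s), positive.
#' @param p0 Baseline risk, in `[0, 1)`.
#' @return Risk ratio(s).
#' @export
odds_to_risk_ratio <- function(or_value, p0) {
  stop_if(any(or_value <= 0), "odds ratios must be positive")
  stop_if(any(p0 < 0) || any(p0 >= 1), "'p0' must be in [0, 1)")
  or_value / (1 - p0 + p0 * or_value)
}

#' Write / read an exposure-response curve as CSV
#'
#' Interchange schema: columns `temp`, `log_rr`, `var`, `ref` (reference
#' temperature repeated). Curves written by other groups can be read back
#' and used for attribution without refitting; such external curves carry
#' pointwise variances only.
#'
#' @param curve An `exposure_response_curve`.
#' @param path File path.
#' @return `write_curve_csv` the path, invisibly; `read_curve_csv` an
#'   `exposure_response_curve` with provenance `"external"`.
#' @export
write_curve_csv <- function(curve, path) {
  df <- data.frame(temp = curve$temp, log_rr = curve$log_rr, var = curve$var,
                   ref = attr(curve, "reference") %||% NA_real_)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  stop_if(!all(c("temp", "log_rr", "var") %in% names(df)),
          "curve CSV needs columns temp, log_rr, var")
  structure(data.frame(temp = df$temp, log_rr = df$log_rr, var = df$var),
            reference = if ("ref" %in% names(df)) df$ref[1] else NA_real_,
            provenance = "external",
            class = c("exposure_response_curve", "data.frame"))
}
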