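#' Assign participant/year/month strata
#'
#' The case-time-series design conditions each participant's outcome series
#' on participant-by-calendar-month baseline risk; the stratum label is
#' `(user, year, month)` of the night's start date. Strata whose outcome
#' total is zero (or all-missing) carry no information about the regression
#' coefficients under the conditional Poisson likelihood and are flagged.
#'
#' @param panel A `nightly_panel` (needs `user`, `date`; uses `osa` or the
#'   column named in `outcome` for informativeness if present).
#' @param outcome Outcome column used to flag non-informative strata.
#' @return A list of class `stratum_index`: integer `stratum` per row,
#'   `labels`, per-stratum `n`, `events`, and logical `informative`.
#' @export
assign_strata <- function(panel, outcome = "osa") {
  stop_if(!all(c("user", "date") %in% names(panel)),
          "panel needs 'user' and 'date'")
  d <- as.Date(panel$date)
  stop_if(any(is.na(d)), "missing dates in panel")
  ud <- unique(d)
  ym_u <- format(ud, "%Y-%m")
  ym_id <- as.integer(factor(ym_u))[match(d, ud)]
  uid <- match(panel$user, unique(panel$user))
  key <- as.numeric(uid) * (max(ym_id) + 1) + ym_id
  ukey <- unique(key)
  stratum <- match(key, ukey)
  first <- match(ukey, key)
  labels <- paste(panel$user[first], ym_u[match(d[first], ud)], sep = ":")
  n_s <- tabulate(stratum)
  if (outcome %in% names(panel)) {
    y <- panel[[outcome]]
    ev <- as.numeric(rowsum(ifelse(is.na(y), 0, y), stratum))
    nonmiss <- as.numeric(rowsum(as.numeric(!is.na(y)), stratum))
    informative <- ev > 0 & nonmiss > 0
  } else {
    ev <- rep(NA_real_, length(n_s))
    informative <- rep(NA, length(n_s))
  }
  structure(list(stratum = stratum, labels = labels, n = n_s,
                 events = ev, informative = informative),
            class = "stratum_index")
}

#' Build the fixed-effect design matrix
#'
#' Assembles, in order: the exposure-by-lag cross-basis, a 4-df natural
#' spline of day of year, day-of-week indicators (Monday dropped), one 4-df
#' natural spline per continuous covariate, and optionally a 4-df spline of
#' within-user total-sleep-time variation (nightly TST minus the user mean).
#' Column-group bookkeeping records which columns belong to the cross-basis
#' so cumulative summaries can address them later. Covariates that are
#' constant over the usable rows are dropped with a warning.
#'
#' @param panel A `nightly_panel`.
#' @param cb Cross-basis matrix from [cross_basis()] (rows matching `panel`).
#' @param covariates Character vector of covariate column names.
#' @param covariate_df Spline df per covariate.
#' @param doy_df Day-of-year spline df (0 drops the term).
#' @param dow Include day-of-week indicators.
#' @param tst_variation Include the within-user sleep-time variation spline.
#' @return A numeric matrix with attribute `"groups"` (named list of column
#'   indices per term) and `"specs"` (frozen spline specs per term).
#' @export
build_design <- function(panel, cb, covariates = character(),
                         covariate_df = 4L, doy_df = 4L, dow = TRUE,
                         tst_variation = FALSE) {
  stop_if(nrow(cb) != nrow(panel), "cross-basis rows must match panel rows")
  blocks <- list(crossbasis = unclass(cb))
  specs <- list(crossbasis = attr(cb, "spec"))

  spline_block <- function(x, df, center_fun = stats::median, spec = NULL) {
    spec <- spec %||% spline_spec_from_data(x, df = df,
                                            center = center_fun(x))
    list(b = unclass(natural_spline_basis(x, spec)), spec = spec)
  }

  if (doy_df > 0) {
    doy <- doy365(as.Date(panel$date))
    doy[is.na(doy)] <- 59L  # leap nights share the Feb 28 seasonal value
    sb <- spline_block(doy, doy_df, spec = attr(panel, "doy_spec"))
    colnames(sb$b) <- paste0("doy", seq_len(ncol(sb$b)))
    blocks$doy <- sb$b
    specs$doy <- sb$spec
  }
  if (isTRUE(dow)) {
    wd <- factor(as.integer(format(as.Date(panel$date), "%u")), levels = 1:7)
    used <- levels(wd)[table(wd) > 0]
    if (length(used) > 1L) {
      mm <- stats::model.matrix(~ wd)[, -1L, drop = FALSE]
      keep <- apply(mm, 2L, function(v) stats::var(v) > 0)
      mm <- mm[, keep, drop = FALSE]
      colnames(mm) <- sub("^wd", "dow", colnames(mm))
      blocks$dow <- mm
    } else {
      warning("panel covers a single weekday; day-of-week block dropped")
    }
  }
  for (cc in covariates) {
    stop_if(!cc %in% names(panel), sprintf("covariate '%s' not in panel", cc))
    x <- panel[[cc]]
    if (stats::var(x, na.rm = TRUE) < .Machine$double.eps) {
      warning(sprintf("covariate '%s' is constant over usable rows; dropped", cc))
      next
    }
    sb <- spline_block(x, covariate_df)
    colnames(sb$b) <- paste0(cc, seq_len(ncol(sb$b)))
    blocks[[cc]] <- sb$b
    specs[[cc]] <- sb$spec
  }
  if (isTRUE(tst_variation)) {
    stop_if(!"tst" %in% names(panel), "no 'tst' column for tst_variation")
    dtst <- panel$tst - stats::ave(panel$tst, panel$user, FUN = mean)
    sb <- spline_block(dtst, covariate_df)
    colnames(sb$b) <- paste0("dtst", seq_len(ncol(sb$b)))
    blocks$tst_variation <- sb$b
    specs$tst_variation <- sb$spec
  }

  X <- do.call(cbind, blocks)
  sizes <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(sizes)
  groups <- Map(function(s, e) seq.int(e - s + 1L, e), sizes, ends)
  attr(X, "groups") <- groups
  attr(X, "specs") <- specs
  X
}

#' Conditional Poisson fit with strata absorbed
#'
#' Maximises the Poisson likelihood with one free intercept per stratum,
#' profiling the intercepts out analytically: with stratum event totals
#' `Y_s` and `S_s = sum over stratum of exp(x'beta)`, the profiled
#' log-likelihood is `sum(y * x'beta) - sum(Y_s * log S_s)` (up to a
#' constant), the likelihood of the case-time-series design. Strata with
#' zero events drop out. Newton-Raphson with step-halving; the covariance is
#' the inverse profiled-likelihood Hessian.
#'
#' @param y Binary (or count) outcome; no missing values.
#' @param X Design matrix (no stratum dummies).
#' @param strata Integer/factor stratum per row, or a `stratum_index`.
#' @param max_iter,tol_score,tol_ll Convergence controls: stop when the
#'   maximum absolute score falls below `tol_score` or the relative
#'   log-likelihood change falls below `tol_ll`.
#' @param protect Column indices that may not be dropped by rank detection
#'   (an error is raised instead); defaults to none.
#' @return An object of class `ctseries_fit`: `coef`, `vcov`, `loglik`,
#'   `iterations`, `converged`, `n`, `n_strata`, `n_dropped_strata`,
#'   `dropped_columns`.
#' @export
fit_conditional_poisson <- function(y, X, strata, max_iter = 100L,
                                    tol_score = 1e-8, tol_ll = 1e-10,
                                    protect = integer()) {
  if (inherits(strata, "stratum_index")) strata <- strata$stratum
  strata <- as.integer(factor(strata))
  stop_if(anyNA(y), "missing outcome values must be dropped before fitting")
  stop_if(length(y) != nrow(X) || length(strata) != nrow(X),
          "y, X, strata must have matching rows")
  X <- as.matrix(X)
  storage.mode(X) <- "double"

  ev <- as.numeric(rowsum(as.numeric(y), strata))
  n_strata <- length(ev)
  keep <- ev[strata] > 0
  stop_if(!any(keep), "no informative stratum (all stratum event totals are zero)")
  yk <- as.numeric(y[keep])
  Xk <- X[keep, , drop = FALSE]
  s <- match(strata[keep], unique(strata[keep]))
  # sparse stratum indicator: one-pass group sums via crossprod
  G <- Matrix::sparseMatrix(i = seq_along(s), j = s, x = 1,
                            dims = c(length(s), max(s)))
  gsum <- function(v) drop(as.matrix(Matrix::crossprod(G, v)))
  Ys <- gsum(yk)

  # rank detection on the Gram matrix (QR with pivoting on X'X, cheap in the
  # number of columns); cross-basis columns are protected
  qrX <- qr(crossprod(Xk))
  dropped <- integer()
  if (qrX$rank < ncol(Xk)) {
    dropped <- sort(qrX$pivot[seq.int(qrX$rank + 1L, ncol(Xk))])
    bad <- intersect(dropped, protect)
    stop_if(length(bad) > 0,
            sprintf("collinear cross-basis column(s) %s cannot be dropped",
                    paste(colnames(Xk)[bad], collapse = ", ")))
    warning(sprintf("dropping %d collinear column(s): %s", length(dropped),
                    paste(colnames(Xk)[dropped], collapse = ", ")))
    Xk <- Xk[, -dropped, drop = FALSE]
  }

  p <- ncol(Xk)
  beta <- numeric(p)
  Xty <- crossprod(Xk, yk)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  H <- diag(p)
  repeat {
    iter <- iter + 1L
    eta <- drop(Xk %*% beta)
    es <- exp(eta)
    Ss <- gsum(es)
    ll <- sum(yk * eta) - sum(Ys * log(Ss))
    w <- Ys[s] * es / Ss[s]
    score <- Xty - crossprod(Xk, w)
    M <- as.matrix(Matrix::crossprod(G, Xk * w))
    H <- crossprod(Xk * sqrt(w)) - crossprod(M / sqrt(Ys))
    if (max(abs(score)) < tol_score ||
        (is.finite(ll_old) && abs(ll - ll_old) < tol_ll * (abs(ll) + 1))) {
      converged <- TRUE
      break
    }
    delta <- tryCatch(solve(H, score), error = function(e) NULL)
    stop_if(is.null(delta), "singular Hessian: model not identified")
    # step-halving on the profiled likelihood
    step <- 1
    repeat {
      beta_new <- beta + step * drop(delta)
      eta_new <- drop(Xk %*% beta_new)
      Ss_new <- gsum(exp(eta_new))
      ll_new <- sum(yk * eta_new) - sum(Ys * log(Ss_new))
      if (is.finite(ll_new) && (ll_new >= ll || step < 1e-4)) break
      step <- step / 2
    }
    beta <- beta_new
    ll_old <- ll
    if (max(abs(beta)) > 50) {
      warning("diverging coefficients: possible separation")
      break
    }
    if (iter >= max_iter) {
      warning(sprintf("no convergence after %d iterations", max_iter))
      break
    }
  }

  vcov <- tryCatch(solve(H), error = function(e) {
    warning("Hessian not invertible; covariance via pseudo-inverse")
    ei <- eigen(H, symmetric = TRUE)
    pos <- ei$values > max(ei$values) * 1e-12
    ei$vectors[, pos, drop = FALSE] %*%
      (t(ei$vectors[, pos, drop = FALSE]) / ei$values[pos])
  })
  vcov <- (vcov + t(vcov)) / 2
  nm <- colnames(Xk) %||% paste0("x", seq_len(p))
  names(beta) <- nm
  dimnames(vcov) <- list(nm, nm)
  structure(
    list(coef = beta, vcov = vcov, loglik = ll, iterations = iter,
         converged = converged, n = length(yk), n_strata = n_strata,
         n_dropped_strata = n_strata - length(Ys), dropped_columns = dropped),
    class = "ctseries_fit"
  )
}

#' Fit the case-time-series model to a nightly panel
#'
#' End-to-end fit: compute the lagged exposure matrix (reusing lag columns
#' carried by the panel when present), freeze the exposure spline (knots at
#' the 25th/50th/75th percentiles, boundary at the range, reference at the
#' 25th percentile unless given), build the cross-basis and adjustment
#' design, drop rows with missing outcome or incomplete lag history, and
#' maximise the absorbed conditional Poisson likelihood. With a binary
#' nightly outcome the exponentiated coefficients are risk ratios.
#'
#' @param panel A `nightly_panel`.
#' @param outcome Outcome column (`"osa"` or `"osa_severe"`).
#' @param exposure Exposure column (`"tmean"`, `"tmin"` or `"tmax"`).
#' @param max_lag Maximum lag (days).
#' @param exposure_spec Optional frozen [spline_spec()]; defaults to the
#'   spec carried by the panel (shared generator/fitter path) or, failing
#'   that, one frozen from the fitted exposures.
#' @param reference Reference temperature; default the spec's center.
#' @param covariates,covariate_df,doy_df,dow,tst_variation Passed to
#'   [build_design()].
#' @param ... Passed to [fit_conditional_poisson()].
#' @return A `ctseries_fit` augmented with the cross-basis bookkeeping
#'   (`cb_spec`, `cb_cols`), the reference, and `p0_ref`, the outcome
#'   prevalence among fitted nights near the reference temperature (used by
#'   the odds-to-risk-ratio conversion).
#' @export
fit_ctseries <- function(panel, outcome = "osa", exposure = "tmean",
                         max_lag = 4L, exposure_spec = NULL, reference = NULL,
                         covariates = character(), covariate_df = 4L,
                         doy_df = 4L, dow = TRUE, tst_variation = FALSE, ...) {
  stop_if(!outcome %in% names(panel), sprintf("no outcome column '%s'", outcome))
  stop_if(!exposure %in% names(panel), sprintf("no exposure column '%s'", exposure))
  panel_exposure_spec <- attr(panel, "exposure_spec")
  panel_doy_spec <- attr(panel, "doy_spec")
  panel <- panel[order(panel$user, as.Date(panel$date)), , drop = FALSE]

  lag_cols <- paste0("tlag", seq_len(max_lag))
  if (exposure == "tmean" && all(lag_cols %in% names(panel)) && max_lag > 0) {
    lagged <- cbind(panel[[exposure]],
                    as.matrix(panel[, lag_cols, drop = FALSE]))
    colnames(lagged) <- paste0("lag", 0:max_lag)
    complete <- stats::complete.cases(lagged)
  } else {
    lagged <- lagged_exposure_matrix(panel[[exposure]], max_lag,
                                     user = panel$user, dates = panel$date)
    complete <- attr(lagged, "complete")
  }

  y <- panel[[outcome]]
  use <- complete & !is.na(y)
  panel_f <- panel[use, , drop = FALSE]
  lagged_f <- lagged[use, , drop = FALSE]

  es <- exposure_spec %||% panel_exposure_spec
  if (is.null(es) || is.null(es$knots)) {
    es <- spline_spec_from_data(as.numeric(lagged_f), df = 4L)
  }
  if (!is.null(reference)) es$center <- reference
  stop_if(is.null(es$center), "no reference temperature available")

  attr(panel_f, "doy_spec") <- panel_doy_spec
  cb <- cross_basis(lagged_f, crossbasis_spec(es, max_lag))
  X <- build_design(panel_f, cb, covariates = covariates,
                    covariate_df = covariate_df, doy_df = doy_df, dow = dow,
                    tst_variation = tst_variation)
  strata <- assign_strata(panel_f, outcome = outcome)
  fit <- fit_conditional_poisson(panel_f[[outcome]], X, strata,
                                 protect = attr(X, "groups")$crossbasis, ...)

  fit$cb_spec <- attr(cb, "spec")
  fit$cb_cols <- attr(X, "groups")$crossbasis
  fit$reference <- fit$cb_spec$exposure_spec$center
  fit$outcome <- outcome
  fit$exposure <- exposure
  near <- abs(panel_f[[exposure]] - fit$reference) <= 1
  fit$p0_ref <- if (sum(near) >= 100) {
    mean(panel_f[[outcome]][near])
  } else {
    mean(panel_f[[outcome]])
  }
  fit$n_rows_dropped <- nrow(panel) - nrow(panel_f)
  fit
}

#' @export
print.ctseries_fit <- function(x, ...) {
  cat("Case-time-series conditional Poisson fit\n")
  cat(sprintf("  rows: %d   strata: %d (dropped %d non-informative)\n",
              x$n, x$n_strata, x$n_dropped_strata))
  cat(sprintf("  coefficients: %d   log-likelihood: %.2f   iterations: %d%s\n",
              length(x$coef), x$loglik, x$iterations,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Independent fits over subgroups
#'
#' Refits the case-time-series model on row subsets defined by a user-level
#' grouping (country, sex, age band, ...). Groups with fewer users than
#' `min_users`, or with no informative stratum, are skipped with a recorded
#' reason.
#'
#' @param panel A `nightly_panel`.
#' @param grouping Column name in `panel`, or a vector of group labels of
#'   length `nrow(panel)`.
#' @param min_users Minimum number of distinct users per fitted group.
#' @param ... Passed to [fit_ctseries()].
#' @return Named list of `ctseries_fit` objects, with attribute `"skipped"`
#'   naming skipped groups and reasons.
#' @export
fit_subgroup <- function(panel, grouping, min_users = 20L, ...) {
  g <- if (is.character(grouping) && length(grouping) == 1L) {
    stop_if(!grouping %in% names(panel), "grouping column not in panel")
    panel[[grouping]]
  } else {
    stop_if(length(grouping) != nrow(panel), "grouping length must match panel")
    grouping
  }
  levels_g <- unique(g)
  stop_if(length(levels_g) == 0L, "empty group set")
  fits <- list()
  skipped <- character()
  for (lev in levels_g) {
    sub <- panel[g == lev, , drop = FALSE]
    nu <- length(unique(sub$user))
    if (nu < min_users) {
      skipped[as.character(lev)] <- sprintf("only %d users (< %d)", nu, min_users)
      next
    }
    f <- tryCatch(fit_ctseries(sub, ...), error = function(e) conditionMessage(e))
    if (is.character(f)) {
      skipped[as.character(lev)] <- f
    } else {
      fits[[as.character(lev)]] <- f
    }
  }
  attr(fits, "skipped") <- skipped
  fits
}
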