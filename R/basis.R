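#' Natural cubic spline specification
#'
#' A frozen description of a natural cubic spline basis: internal knots,
#' boundary knots, and an optional centering value at which every basis
#' column vanishes. Freezing the knots (rather than recomputing them from
#' each new data vector) lets the same basis be shared between the synthetic
#' cohort generator, the model fit, and curve prediction.
#'
#' @param df Degrees of freedom (number of basis columns). Used only when
#'   `knots` is `NULL`, in which case `df - 1` internal knots are placed at
#'   equally spaced quantiles of the data passed to [spline_spec_from_data()].
#' @param knots Internal knot locations (strictly increasing).
#' @param boundary Length-2 boundary knots; the basis is linear beyond them.
#' @param center Centering value (e.g. the reference temperature), or `NULL`.
#' @return An object of class `spline_spec`.
#' @export
spline_spec <- function(df = 4L, knots = NULL, boundary = NULL, center = NULL) {
  if (!is.null(knots)) {
    stop_if(is.unsorted(knots, strictly = TRUE), "knots must be strictly increasing")
    df <- length(knots) + 1L
    if (!is.null(boundary)) {
      stop_if(length(boundary) != 2L || boundary[1] >= boundary[2],
              "'boundary' must be two increasing values")
      stop_if(any(knots <= boundary[1]) || any(knots >= boundary[2]),
              "internal knots must lie strictly inside the boundary knots")
    }
  }
  stop_if(!is.numeric(df) || df < 1, "'df' must be an integer >= 1")
  structure(list(df = as.integer(df), knots = knots, boundary = boundary,
                 center = center),
            class = "spline_spec")
}

#' Freeze a spline specification on observed data
#'
#' Places `df - 1` internal knots at equally spaced quantiles of `x`
#' (25th/50th/75th percentiles for the default 4 df) and boundary knots at
#' the data range, the usual choice in distributed-lag temperature models.
#'
#' @param x Numeric data vector.
#' @param df Degrees of freedom.
#' @param center Centering value; defaults to the 25th percentile of `x`
#'   (the reference temperature convention used throughout).
#' @return A fully specified `spline_spec`.
#' @export
spline_spec_from_data <- function(x, df = 4L, center = NULL) {
  x <- x[is.finite(x)]
  stop_if(length(unique(x)) < df + 1L,
          "not enough distinct values to place the requested knots")
  probs <- seq_len(df - 1L) / df
  kn <- unname(stats::quantile(x, probs))
  if (any(duplicated(kn)) || any(kn <= min(x)) || any(kn >= max(x))) {
    # zero-inflated or heavily tied data: fall back to quantiles of the
    # distinct values so knots stay strictly increasing and interior
    kn <- unname(stats::quantile(unique(x), probs))
  }
  stop_if(any(duplicated(kn)) || any(kn <= min(x)) || any(kn >= max(x)),
          "duplicated knots: too few distinct x values")
  spline_spec(df = df, knots = kn, boundary = range(x),
              center = center %||% unname(stats::quantile(x, 0.25)))
}

#' Evaluate a natural cubic spline basis
#'
#' Columns form a natural cubic spline basis: piecewise cubic, twice
#' continuously differentiable inside the boundary knots and linear beyond
#' them. When the specification carries a centering value, the row of basis
#' values at that value is subtracted from every row, so the centered basis
#' is identically zero at the center.
#'
#' @param x Numeric vector at which to evaluate the basis.
#' @param spec A [spline_spec()]; if its knots are unset they are frozen
#'   from `x` first.
#' @return A numeric matrix with `length(x)` rows and `spec$df` columns
#'   (class `basis_matrix`), with the resolved `spline_spec` attached as
#'   attribute `"spec"`.
#' @export
natural_spline_basis <- function(x, spec = spline_spec()) {
  stopifnot(inherits(spec, "spline_spec"))
  if (is.null(spec$knots)) spec <- spline_spec_from_data(x, df = spec$df,
                                                         center = spec$center)
  boundary <- spec$boundary %||% range(x[is.finite(x)])
  eval_ns <- function(v) {
    unclass(splines::ns(v, knots = spec$knots, Boundary.knots = boundary,
                        intercept = FALSE))[, , drop = FALSE]
  }
  # long vectors usually repeat few distinct values (shared country weather):
  # evaluate on the unique values and expand by index
  if (length(x) > 4096L) {
    ux <- unique(x)
    b <- eval_ns(ux)[match(x, ux), , drop = FALSE]
  } else {
    b <- eval_ns(x)
  }
  if (!is.null(spec$center)) {
    b0 <- as.numeric(eval_ns(spec$center))
    b <- b - rep(b0, each = nrow(b))
  }
  dimnames(b) <- list(NULL, paste0("b", seq_len(ncol(b))))
  spec$boundary <- boundary
  attr(b, "spec") <- spec
  class(b) <- c("basis_matrix", "matrix")
  b
}

#' Lagged exposure matrix
#'
#' Column `lag ℓ` holds the exposure `ℓ` days before each observation,
#' computed within user over a contiguous nightly sequence. The first
#' `max_lag` rows of each user have incomplete lag histories and are flagged
#' (attribute `"complete"`) for exclusion from fitting.
#'
#' @param x Numeric exposure series (daily, contiguous within user).
#' @param max_lag Maximum lag in days (>= 0).
#' @param user Optional vector of user ids grouping `x`; `NULL` treats `x`
#'   as a single series.
#' @param dates Optional dates used to verify within-user contiguity.
#' @return Matrix with `max_lag + 1` columns `lag0 ... lag<max_lag>` and a
#'   logical attribute `"complete"` marking rows with full lag history.
#' @export
lagged_exposure_matrix <- function(x, max_lag, user = NULL, dates = NULL) {
  stop_if(max_lag < 0, "'max_lag' must be >= 0")
  max_lag <- as.integer(max_lag)
  if (is.null(user)) user <- rep(1L, length(x))
  stop_if(length(user) != length(x), "'user' must match 'x' in length")
  if (!is.null(dates)) {
    d <- as.integer(as.Date(dates))
    gaps <- unlist(tapply(d, user, function(v) diff(v) != 1L), use.names = FALSE)
    stop_if(any(gaps), "date gaps within user; insert explicit break markers")
  }
  idx <- seq_along(x)
  within <- stats::ave(idx, user, FUN = seq_along)
  out <- matrix(NA_real_, length(x), max_lag + 1L,
                dimnames = list(NULL, paste0("lag", 0:max_lag)))
  for (l in 0:max_lag) {
    src <- idx - l
    ok <- within > l
    out[ok, l + 1L] <- x[src[ok]]
  }
  attr(out, "complete") <- within > max_lag
  out
}

#' Cross-basis specification
#'
#' Describes the exposure x lag tensor basis of a distributed-lag non-linear
#' model: a natural cubic spline over the exposure dimension and one
#' indicator per lag over the lag dimension (lags 0 to `max_lag`), centered
#' at a reference temperature.
#'
#' @param exposure_spec A [spline_spec()] for the exposure dimension; its
#'   `center` is the reference temperature.
#' @param max_lag Maximum lag in days (default 4, the lag window over which
#'   temperature affects the nightly outcome).
#' @return An object of class `crossbasis_spec`.
#' @export
crossbasis_spec <- function(exposure_spec = spline_spec(), max_lag = 4L) {
  stopifnot(inherits(exposure_spec, "spline_spec"))
  stop_if(max_lag < 0, "'max_lag' must be >= 0")
  structure(list(exposure_spec = exposure_spec, max_lag = as.integer(max_lag)),
            class = "crossbasis_spec")
}

#' Build the exposure x lag cross-basis
#'
#' With an indicator lag basis, the cross-basis column `(j, ℓ)` is exposure
#' basis function `j` evaluated at the lag-`ℓ` exposure, centered at the
#' reference temperature; a row whose exposures all equal the reference maps
#' to the zero vector, so cumulative log-RR at the reference is identically
#' zero for any coefficient vector.
#'
#' @param lagged Matrix from [lagged_exposure_matrix()] with `max_lag + 1`
#'   columns.
#' @param spec A [crossbasis_spec()]; the exposure spline must be frozen
#'   (knots set), otherwise it is frozen on the lag-0 column.
#' @return Matrix with `df * (max_lag + 1)` columns named `b<j>.lag<ℓ>`,
#'   with the resolved spec attached as attribute `"spec"`.
#' @export
cross_basis <- function(lagged, spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  stop_if(ncol(lagged) != spec$max_lag + 1L,
          "lagged matrix must have max_lag + 1 columns")
  es <- spec$exposure_spec
  if (is.null(es$knots)) {
    es <- spline_spec_from_data(lagged[, 1L], df = es$df, center = es$center)
  }
  stop_if(is.null(es$center), "cross-basis requires a reference (center) temperature")
  blocks <- vector("list", spec$max_lag + 1L)
  for (l in 0:spec$max_lag) {
    bl <- natural_spline_basis(lagged[, l + 1L], es)
    colnames(bl) <- sprintf("b%d.lag%d", seq_len(ncol(bl)), l)
    blocks[[l + 1L]] <- unclass(bl)
  }
  out <- do.call(cbind, blocks)
  spec$exposure_spec <- es
  attr(out, "spec") <- spec
  class(out) <- c("basis_matrix", "matrix")
  out
}
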