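# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their configuration (including the seed) and do not disturb the caller's
#' RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as_seed(seed))
  expr
}

# Map any numeric to a valid 32-bit seed (R integers are 32-bit).
as_seed <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
  as.integer(abs(x) %% .Machine$integer.max)
}

# Deterministic per-unit substream: changing the number of units never
# perturbs the draws of existing units.
unit_seed <- function(seed, unit) {
  as_seed((as.double(seed) * 1000003 + as.double(unit) * 7919) %% 2147483647)
}

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

assert_prob <- function(x, name) {
  stop_if(!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1),
          sprintf("'%s' must be a probability in [0, 1]", name))
  invisible(x)
}

assert_finite <- function(x, name) {
  stop_if(!is.numeric(x) || any(!is.finite(x)),
          sprintf("'%s' must be finite numeric", name))
  invisible(x)
}

# Day of year on a fixed 365-day calendar: Feb 29 maps to NA so leap days
# can be dropped before any day-of-year aggregation.
doy365 <- function(dates) {
  m <- as.POSIXlt(dates)$mon + 1L
  d <- as.POSIXlt(dates)$mday
  cum <- c(0L, cumsum(c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L)))
  out <- cum[m] + d
  out[m == 2L & d == 29L] <- NA_integer_
  out
}
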