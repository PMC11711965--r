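#' Ordinary least-squares line fit
#'
#' Thin wrapper around [stats::lm()] returning the quantities the tracer
#' regressions use: slope, intercept, slope standard error, R^2 and n.
#' Degenerate predictors (all x equal) are an explicit error rather than a
#' silent NaN.
#'
#' @param x,y Numeric vectors of equal length.
#' @param with_intercept Fit `y ~ x` (default) or `y ~ 0 + x`.
#' @return An object of class `regression_fit`: list with `slope`,
#'   `intercept` (0 for origin fits), `slope_se`, `r_squared`, `n`,
#'   `with_intercept`.
#' @export
fit_line <- function(x, y, with_intercept = TRUE) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  n_min <- if (with_intercept) 3L else 2L
  if (n < n_min) {
    stop(sprintf("need at least %d points, got %d", n_min, n), call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("degenerate predictor: all x values are equal", call. = FALSE)
  }
  fit <- if (with_intercept) lm(y ~ x) else lm(y ~ 0 + x)
  sm <- summary(fit)
  cf <- sm$coefficients
  slope_row <- if (with_intercept) 2L else 1L
  out <- list(
    slope = unname(cf[slope_row, 1L]),
    intercept = if (with_intercept) unname(cf[1L, 1L]) else 0,
    slope_se = unname(cf[slope_row, 2L]),
    r_squared = sm$r.squared,
    n = n,
    with_intercept = with_intercept
  )
  class(out) <- "regression_fit"
  out
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "<regression_fit> y = %.4g x %s (slope SE %.3g, R2 %.3f, n = %d)\n",
    x$slope,
    if (x$with_intercept) sprintf("%+.4g", x$intercept) else "(through origin)",
    x$slope_se, x$r_squared, x$n
  ))
  invisible(x)
}
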