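#' Fit a cubic smoothing spline
#'
#' Natural cubic smoothing spline minimising
#' \deqn{\sum_i (y_i - f(x_i))^2 + \lambda \int f''(t)^2 dt}
#' with knots at every data point, computed by the Reinsch banded algorithm
#' in O(n). Unlike [stats::smooth.spline()], no knot thinning is performed,
#' so near-interpolating ("subtle") smoothing of long audio signals is
#' possible at full resolution.
#'
#' @param x strictly increasing numeric vector of abscissae.
#' @param y numeric responses, same length as `x`.
#' @param lambda nonnegative roughness penalty, in units of `x` cubed
#'   (for unit-spaced samples, `lambda ~ 1e-4` leaves the speech band
#'   essentially untouched while attenuating near-Nyquist noise).
#' @return object of class `smoothing_spline` with knots `x`, fitted values
#'   `f` and second derivatives `M` (natural boundary: zero at the ends).
#' @export
smoothing_spline <- function(x, y, lambda) {
  stopifnot(length(x) == length(y), length(x) >= 2L, lambda >= 0)
  fit <- .reinsch_fit_cpp(as.numeric(x), as.numeric(y), lambda)
  structure(list(x = as.numeric(x), f = fit$f, M = fit$M, lambda = lambda),
            class = "smoothing_spline")
}

#' Evaluate a fitted smoothing spline
#'
#' Piecewise-cubic evaluation between knots; linear extrapolation outside
#' the knot range (natural spline boundary behaviour).
#'
#' @param object a `smoothing_spline` fit.
#' @param x points at which to evaluate.
#' @param ... unused.
#' @return numeric vector of spline values at `x`.
#' @export
predict.smoothing_spline <- function(object, x, ...) {
  .spline_eval_cpp(object$x, object$f, object$M, as.numeric(x))
}
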