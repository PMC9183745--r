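#' Logistic decline model parameters
#'
#' Container for the three parameters of the sigmoidal decline model
#' \deqn{y = \frac{y_{max}}{1 + e^{(x - D50)/dx}}}{y = ymax / (1 + exp((x - D50)/dx))}
#' where `y` is the total ALSFRS-R score at `x` months since symptom onset,
#' `y_max` is the theoretical maximum score (48 for the full instrument),
#' `d50` is the time in months at which the modelled score falls to
#' `y_max / 2` (24 points), and `dx` is the steepness denominator in months:
#' smaller `dx` means a sharper transition. The tangent slope at the
#' midpoint is `-y_max / (4 * dx)` points/month (see [midpoint_slope()]).
#'
#' @param d50 Midpoint time in months since onset; must be positive.
#' @param dx Steepness denominator in months; must be positive. A positive
#'   `dx` gives a decaying curve, the only shape accepted as a valid
#'   parameterisation; growth-shaped curves are treated as fit failures
#'   upstream, never as parameters.
#' @param y_max Theoretical maximum score, default 48.
#' @return An object of class `logistic_params`.
#' @examples
#' p <- logistic_params(d50 = 51.724, dx = 17.184)
#' predict_score(p, 40)
#' @export
logistic_params <- function(d50, dx, y_max = 48) {
  for (nm in c("d50", "dx", "y_max")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_d50(sprintf("`%s` must be a single finite number", nm), "validation")
    }
  }
  if (d50 <= 0) stop_d50("`d50` must be positive (months since onset)", "validation")
  if (dx <= 0) stop_d50("`dx` must be positive; decay requires dx > 0", "validation")
  if (y_max <= 0) stop_d50("`y_max` must be positive", "validation")
  structure(list(y_max = y_max, d50 = d50, dx = dx), class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf(
    "<logistic_params>  y_max = %g, D50 = %g months, dx = %g months (midpoint slope %.4f pts/month)\n",
    x$y_max, x$d50, x$dx, midpoint_slope(x)
  ))
  invisible(x)
}

## Unvalidated vectorised kernel shared with the fitting hot loop.
## The exponent is clamped so exp() never returns Inf/NaN: predictions
## saturate to the asymptotes y_max and 0 for extreme x.
.logistic <- function(x, y_max, d50, dx) {
  z <- (x - d50) / dx
  z <- pmin(pmax(z, -745), 709)
  y_max / (1 + exp(z))
}

#' Predicted ALSFRS-R score at a given time
#'
#' Evaluates the logistic decline curve. Strictly decreasing in `x`,
#' bounded in `(0, y_max)`; extreme times saturate smoothly to the
#' asymptotes rather than overflowing.
#'
#' @param params A [logistic_params()] object.
#' @param x Months since symptom onset (vectorised); must be positive and
#'   finite.
#' @return Numeric vector of predicted total scores.
#' @export
predict_score <- function(params, x) {
  check_params(params)
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    stop_d50("`x` must be finite months since onset", "validation")
  }
  if (any(x <= 0)) stop_d50("`x` must be positive (months since onset)", "validation")
  .logistic(x, params$y_max, params$d50, params$dx)
}

#' Time at which the modelled score reaches a given value
#'
#' Analytic inverse of [predict_score()]:
#' `x = d50 + dx * log(y_max / y - 1)`. Only scores strictly inside
#' `(0, y_max)` are attainable; the asymptotes are reached in the limit
#' only.
#'
#' @inheritParams predict_score
#' @param y Target total score, strictly between 0 and `y_max`.
#' @return Months since onset at which the curve passes through `y`.
#' @export
time_at_score <- function(params, y) {
  check_params(params)
  if (!is.numeric(y) || length(y) == 0L || any(!is.finite(y))) {
    stop_d50("`y` must be a finite score", "validation")
  }
  if (any(y <= 0) || any(y >= params$y_max)) {
    stop_d50(sprintf("`y` must lie strictly inside (0, %g); the asymptotes are never attained",
                     params$y_max), "domain")
  }
  params$d50 + params$dx * log(params$y_max / y - 1)
}

#' Tangent slope of the decline curve at its midpoint
#'
#' The derivative of the logistic curve at `x = d50`, i.e. at score
#' `y_max / 2`: `-y_max / (4 * dx)` points/month. This is the decline
#' *rate* that corresponds to a shape parameter `dx`; the two are often
#' conflated in clinical shorthand, so both are exposed explicitly.
#'
#' @inheritParams predict_score
#' @return A negative scalar, points per month.
#' @export
midpoint_slope <- function(params) {
  check_params(params)
  -params$y_max / (4 * params$dx)
}

#' Truncate a value toward zero for display
#'
#' Display convention for reported curve values: truncation toward zero at
#' a fixed number of decimal places (so 31.88 -> 31 and 0.99 -> 0.9), with
#' negative inputs clamped to 0 since displayed scores cannot be negative.
#' Internal computation always keeps full precision; this is applied only
#' when printing score predictions.
#'
#' @param value Finite numeric vector.
#' @param decimals Non-negative integer number of decimal places to keep.
#' @return Numeric vector truncated at the requested decimal place.
#' @examples
#' truncate_display(31.88)        # 31
#' truncate_display(0.9936, 1)    # 0.9
#' @export
truncate_display <- function(value, decimals = 0L) {
  if (!is.numeric(value) || any(!is.finite(value))) {
    stop_d50("`value` must be finite", "validation")
  }
  if (!is.numeric(decimals) || length(decimals) != 1L || decimals < 0 ||
      decimals != trunc(decimals)) {
    stop_d50("`decimals` must be a non-negative integer", "validation")
  }
  f <- 10^decimals
  pmax(trunc(value * f) / f, 0)
}

check_params <- function(params) {
  if (!inherits(params, "logistic_params")) {
    stop_d50("`params` must be created with logistic_params()", "validation")
  }
  invisible(params)
}

stop_d50 <- function(msg, subclass, call = sys.call(-1)) {
  stop(errorCondition(msg,
                      class = c(paste0("d50fit_", subclass, "_error"), "d50fit_error"),
                      call = call))
}
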