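#' Conventional linear decline rate of a trajectory
#'
#' The simple linear ALSFRS-R progression rate in points lost per month,
#' used to seed the nonlinear fit. Two estimators are provided:
#'
#' * `two_point` (default): rise over run between the first and last
#'   recorded visits, `(y_first - y_last) / (x_last - x_first)`. Needs at
#'   least two visits.
#' * `onset_anchored`: the field-standard rate anchored at full function
#'   at symptom onset, `(48 - y_first) / x_first`, computable from a
#'   single visit.
#'
#' Both are reported as positive decline rates. A flat trajectory yields
#' a rate of exactly 0 (the degenerate case callers must handle); a
#' trajectory that *improves* overall yields a negative value.
#'
#' @param trajectory An [als_trajectory()].
#' @param method `"two_point"` or `"onset_anchored"`.
#' @return Decline rate in points/month (positive for decliners).
#' @export
conventional_slope <- function(trajectory, method = c("two_point", "onset_anchored")) {
  check_trajectory(trajectory)
  method <- match.arg(method)
  n <- n_visits(trajectory)
  if (method == "two_point") {
    if (n < 2L) stop_d50("two_point slope needs at least two visits", "validation")
    run <- trajectory$months[n] - trajectory$months[1]
    if (run <= 0) stop_d50("elapsed time between first and last visit must be positive", "validation")
    (trajectory$scores[1] - trajectory$scores[n]) / run
  } else {
    (48 - trajectory$scores[1]) / trajectory$months[1]
  }
}

#' Initial D50 from linear extrapolation to the midpoint score
#'
#' Locates the time at which the straight-line decline passes through the
#' model midpoint of 24 points. When the observed scores cross 24, the
#' crossing is linearly interpolated between the bracketing visits; a
#' visit scoring exactly 24 is used directly. Otherwise the trajectory is
#' extrapolated from the last visit along the conventional slope:
#' `x_last + (y_last - 24) / slope` (which reaches back in time when the
#' last score is already below 24). In the rare case where backward
#' extrapolation lands at or before onset, the estimate is floored at
#' half the first visit time so that the seed remains a valid positive
#' time.
#'
#' @inheritParams conventional_slope
#' @param slope Positive conventional decline rate in points/month.
#' @return Initial estimate of D50 in months (> 0).
#' @export
initial_d50 <- function(trajectory, slope) {
  check_trajectory(trajectory)
  check_slope(slope)
  m <- trajectory$months
  y <- trajectory$scores
  n <- length(m)
  at24 <- which(y == 24)
  if (length(at24) > 0L) return(m[at24[1]])
  cross <- which((y[-n] - 24) * (y[-1] - 24) < 0)
  if (length(cross) > 0L) {
    i <- cross[1]
    # linear interpolation between the bracketing visits
    return(m[i] + (y[i] - 24) * (m[i + 1] - m[i]) / (y[i] - y[i + 1]))
  }
  est <- m[n] + (y[n] - 24) / slope
  if (est <= 0) est <- m[1] / 2
  est
}

#' Initial dx from the conventional slope
#'
#' Two seeding conventions for the steepness parameter:
#'
#' * `mode = "paper"`: the conventional slope (points/month) is passed
#'   through verbatim as the initial `dx`. This mirrors how published
#'   per-patient analyses of this model have seeded the optimiser, and it
#'   reproduces their characteristic failure mode: a slow decliner's rate
#'   (say 0.2 points/month), read as a steepness denominator of 0.2
#'   months, describes a near-step curve on whose flat plateau the
#'   optimiser finds no gradient and stalls at the seed.
#' * `mode = "converted"` (default): `48 / (4 * slope)`, the steepness
#'   denominator whose midpoint tangent equals the conventional slope --
#'   the dimensionally consistent seed, recommended for new analyses.
#'
#' @param slope Positive conventional decline rate in points/month.
#' @param mode `"converted"` or `"paper"`.
#' @return Initial `dx` (months in converted mode; points/month read as
#'   months in paper mode).
#' @export
initial_dx <- function(slope, mode = c("converted", "paper")) {
  check_slope(slope)
  mode <- match.arg(mode)
  if (mode == "paper") slope else 48 / (4 * slope)
}

#' Initial parameter estimates for the logistic fit
#'
#' Bundles [conventional_slope()], [initial_d50()] and [initial_dx()]
#' into the seed used by [fit_patient()]. A flat or improving trajectory
#' (slope <= 0) yields a result flagged `zero_slope = TRUE` with `NA`
#' seeds rather than an error, so cohort-level drivers can record the
#' patient as unfittable and move on.
#'
#' @inheritParams conventional_slope
#' @param mode Seeding convention for `dx`; see [initial_dx()].
#' @return An object of class `initial_estimates` with fields
#'   `conventional_slope`, `init_dx`, `init_d50`, `method`, `mode`,
#'   `zero_slope`.
#' @export
initial_estimates <- function(trajectory, method = c("two_point", "onset_anchored"),
                              mode = c("converted", "paper")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  slope <- conventional_slope(trajectory, method)
  if (slope <= 0) {
    out <- list(conventional_slope = slope, init_dx = NA_real_,
                init_d50 = NA_real_, method = method, mode = mode,
                zero_slope = TRUE)
  } else {
    out <- list(conventional_slope = slope,
                init_dx = initial_dx(slope, mode),
                init_d50 = initial_d50(trajectory, slope),
                method = method, mode = mode, zero_slope = FALSE)
  }
  structure(out, class = "initial_estimates")
}

#' @export
print.initial_estimates <- function(x, ...) {
  if (x$zero_slope) {
    cat(sprintf("<initial_estimates> [%s/%s] zero or negative conventional slope (%.4g pts/month): no usable seed\n",
                x$method, x$mode, x$conventional_slope))
  } else {
    cat(sprintf("<initial_estimates> [%s/%s] slope %.4g pts/month -> init dx %.4g, init D50 %.4g months\n",
                x$method, x$mode, x$conventional_slope, x$init_dx, x$init_d50))
  }
  invisible(x)
}

check_slope <- function(slope) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope)) {
    stop_d50("`slope` must be a single finite number", "validation")
  }
  if (slope <= 0) {
    stop_d50("conventional slope must be positive (flat trajectories carry the zero-slope flag instead)",
             "zero_slope")
  }
  invisible(slope)
}
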