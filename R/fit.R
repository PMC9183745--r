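#' Configuration for per-patient logistic fitting
#'
#' @param seed Integer seed governing every stochastic step downstream
#'   (bootstrap resampling). Required so that all runs are reproducible;
#'   it is echoed into every result.
#' @param constrain_ymax Keep the curve ceiling constrained to `(0, 48]`
#'   (default). Turning this off is the diagnostic mode of
#'   [diagnose_unconstrained()].
#' @param fix_ymax_at_48 Fix the ceiling at the instrument maximum of 48
#'   (default) so only `d50` and `dx` are optimised; when `FALSE` (and
#'   `constrain_ymax = TRUE`) the ceiling is a third free parameter
#'   bounded in `(0, 48]`.
#' @param bounds_d50,bounds_dx Positive finite search intervals for the
#'   midpoint time and steepness denominator, in months.
#' @param init_mode Seeding convention for `dx`; see [initial_dx()].
#' @param init_method Conventional-slope estimator; see
#'   [conventional_slope()].
#' @param max_iterations Optimiser iteration cap.
#' @param tolerance Convergence/closeness tolerance used when deciding
#'   whether a fit stalled at its seed (`degenerate_initial`) or sits on
#'   a bound.
#' @param n_bootstrap Number of case-resampling bootstrap replicates.
#' @param ci_level Bootstrap percentile interval level, in (0, 1).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(seed,
                       constrain_ymax = TRUE,
                       fix_ymax_at_48 = TRUE,
                       bounds_d50 = c(1e-6, 600),
                       bounds_dx = c(1e-3, 200),
                       init_mode = c("converted", "paper"),
                       init_method = c("two_point", "onset_anchored"),
                       max_iterations = 500L,
                       tolerance = 1e-6,
                       n_bootstrap = 1000L,
                       ci_level = 0.95) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_d50("`seed` is required and must be a single integer", "validation")
  }
  init_mode <- match.arg(init_mode)
  init_method <- match.arg(init_method)
  for (b in list(bounds_d50, bounds_dx)) {
    if (length(b) != 2L || any(!is.finite(b)) || b[1] <= 0 || b[2] <= b[1]) {
      stop_d50("parameter bounds must be positive finite intervals (lo, hi)", "validation")
    }
  }
  if (ci_level <= 0 || ci_level >= 1) stop_d50("`ci_level` must lie in (0, 1)", "validation")
  if (n_bootstrap < 1) stop_d50("`n_bootstrap` must be at least 1", "validation")
  structure(list(seed = as.integer(seed),
                 constrain_ymax = isTRUE(constrain_ymax),
                 fix_ymax_at_48 = isTRUE(fix_ymax_at_48),
                 bounds_d50 = as.numeric(bounds_d50),
                 bounds_dx = as.numeric(bounds_dx),
                 init_mode = init_mode,
                 init_method = init_method,
                 max_iterations = as.integer(max_iterations),
                 tolerance = as.numeric(tolerance),
                 n_bootstrap = as.integer(n_bootstrap),
                 ci_level = as.numeric(ci_level)),
            class = "fit_config")
}

check_config <- function(config) {
  if (!inherits(config, "fit_config")) {
    stop_d50("`config` must be created with fit_config()", "validation")
  }
  invisible(config)
}

## ---- internal vector-level machinery -------------------------------------
## The bootstrap refits resampled visit sets that may contain duplicated
## times, which the als_trajectory class rightly refuses; these helpers
## therefore work on raw (x, y) vectors sorted by time.

.conv_slope_xy <- function(x, y) {
  n <- length(x)
  (y[1] - y[n]) / (x[n] - x[1])
}

.init_d50_xy <- function(x, y, slope) {
  n <- length(x)
  at24 <- which(y == 24)
  if (length(at24) > 0L) return(x[at24[1]])
  cross <- which((y[-n] - 24) * (y[-1] - 24) < 0)
  if (length(cross) > 0L) {
    i <- cross[1]
    return(x[i] + (y[i] - 24) * (x[i + 1] - x[i]) / (y[i] - y[i + 1]))
  }
  est <- x[n] + (y[n] - 24) / slope
  if (est <= 0) est <- x[1] / 2
  est
}

.init_dx_xy <- function(slope, mode) {
  if (mode == "paper") slope else 48 / (4 * slope)
}

## SSE and its analytic gradient. theta is c(d50, dx) when ymax is fixed,
## else c(ymax, d50, dx).
.sse_fun <- function(theta, x, y, ymax_fixed) {
  if (is.null(ymax_fixed)) {
    f <- .logistic(x, theta[1], theta[2], theta[3])
  } else {
    f <- .logistic(x, ymax_fixed, theta[1], theta[2])
  }
  sum((y - f)^2)
}

.sse_grad <- function(theta, x, y, ymax_fixed) {
  if (is.null(ymax_fixed)) {
    ymax <- theta[1]; d50 <- theta[2]; dx <- theta[3]
  } else {
    ymax <- ymax_fixed; d50 <- theta[1]; dx <- theta[2]
  }
  z <- pmin(pmax((x - d50) / dx, -745), 709)
  E <- exp(z)
  inv <- 1 / (1 + E)
  f <- ymax * inv
  r <- y - f
  s <- E * inv * inv                      # logistic density factor, ~0 at saturation
  s[!is.finite(s)] <- 0
  g_d50 <- -2 * sum(r * (ymax * s / dx))
  g_dx  <- -2 * sum(r * (ymax * s * (x - d50) / dx^2))
  if (is.null(ymax_fixed)) {
    g_ymax <- -2 * sum(r * inv)
    c(g_ymax, g_d50, g_dx)
  } else {
    c(g_d50, g_dx)
  }
}

## Bounded least-squares on raw vectors. Returns parameters, status and
## bookkeeping; `inits` must carry init_d50/init_dx (and the slope).
.fit_xy <- function(x, y, inits, config, ymax_mode = c("fixed", "bounded", "free")) {
  ymax_mode <- match.arg(ymax_mode)
  lo_d50 <- config$bounds_d50[1]; hi_d50 <- config$bounds_d50[2]
  lo_dx <- config$bounds_dx[1]; hi_dx <- config$bounds_dx[2]
  clamp <- function(v, lo, hi) min(max(v, lo), hi)
  d50_0 <- clamp(inits$init_d50, lo_d50, hi_d50)
  dx_0 <- clamp(inits$init_dx, lo_dx, hi_dx)

  if (ymax_mode == "fixed") {
    theta0 <- c(d50_0, dx_0)
    lower <- c(lo_d50, lo_dx); upper <- c(hi_d50, hi_dx)
    ymax_fixed <- 48
  } else if (ymax_mode == "bounded") {
    theta0 <- c(48, d50_0, dx_0)
    lower <- c(1e-6, lo_d50, lo_dx); upper <- c(48, hi_d50, hi_dx)
    ymax_fixed <- NULL
  } else {
    theta0 <- c(48, d50_0, dx_0)
    lower <- c(-Inf, lo_d50, lo_dx); upper <- c(Inf, hi_d50, hi_dx)
    ymax_fixed <- NULL
  }

  run_optim <- function(start) {
    tryCatch(
      stats::optim(start, .sse_fun, .sse_grad, x = x, y = y,
                   ymax_fixed = ymax_fixed,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = config$max_iterations,
                                  factr = 10, pgtol = 1e-14)),
      error = function(e) NULL)
  }

  sse0 <- .sse_fun(theta0, x, y, ymax_fixed)
  opt <- run_optim(theta0)
  if (is.null(opt)) {
    return(list(ok = FALSE, status = "failed", reason = "optimizer error",
                theta = theta0, sse = sse0, sse_init = sse0, n_iterations = 0L,
                ymax_fixed = ymax_fixed))
  }

  tol <- config$tolerance
  stalled <- max(abs(opt$par - theta0) / (1 + abs(theta0))) < tol &&
    opt$value >= sse0 - 1e-12 * (1 + sse0)

  ## Safeguarded restart: with very sparse visit sets the SSE surface has
  ## a spurious step-curve basin at tiny dx that an overshooting first
  ## step can fall into. Probe a dx ladder at the seed and fitted d50
  ## (cheap function evaluations) and re-optimise only when a probe
  ## strictly beats the current optimum. A seeded run that stalled at its
  ## initials is reported as-is: that stall is a finding, not a defect to
  ## paper over.
  if (!stalled) {
    dx_ladder <- c(1.5, 3, 6, 12, 24, 48, 96)
    probes <- rbind(
      do.call(rbind, lapply(dx_ladder, function(dd) {
        th <- opt$par
        th[length(th)] <- min(max(dd, lo_dx), hi_dx)
        th
      })),
      do.call(rbind, lapply(dx_ladder, function(dd) {
        th <- theta0
        th[length(th)] <- min(max(dd, lo_dx), hi_dx)
        th
      })))
    probe_sse <- apply(probes, 1, .sse_fun, x = x, y = y, ymax_fixed = ymax_fixed)
    best <- which.min(probe_sse)
    if (probe_sse[best] < opt$value - 1e-12 * (1 + opt$value)) {
      opt2 <- run_optim(probes[best, ])
      if (!is.null(opt2) && opt2$value < opt$value) {
        opt2$counts[1] <- opt2$counts[1] + opt$counts[1]
        opt <- opt2
      }
    }
  }

  theta <- opt$par
  sse <- opt$value
  tol <- config$tolerance
  at_init <- max(abs(theta - theta0) / (1 + abs(theta0))) < tol
  improved <- sse < sse0 - 1e-12 * (1 + sse0)
  near <- function(v, b) is.finite(b) && abs(v - b) < tol * (1 + abs(b))
  on_bound <- any(mapply(near, theta, lower)) || any(mapply(near, theta, upper))
  ## The very tight factr makes L-BFGS-B occasionally end with an
  ## "abnormal line search" report *at* the minimum; a negligible final
  ## gradient identifies those terminations as successes.
  g_final <- .sse_grad(theta, x, y, ymax_fixed)
  optimiser_ok <- opt$convergence == 0 ||
    max(abs(g_final)) <= 1e-4 * (1 + abs(sse))

  status <- if (at_init && !improved) "degenerate_initial"
            else if (on_bound) "boundary"
            else if (optimiser_ok && sse <= sse0) "converged"
            else "failed"
  list(ok = TRUE, status = status, reason = NULL, theta = theta, sse = sse,
       sse_init = sse0, n_iterations = unname(opt$counts[1]),
       ymax_fixed = ymax_fixed)
}

.theta_unpack <- function(res) {
  if (is.null(res$ymax_fixed)) {
    list(y_max = res$theta[1], d50 = res$theta[2], dx = res$theta[3])
  } else {
    list(y_max = res$ymax_fixed, d50 = res$theta[1], dx = res$theta[2])
  }
}

## ---- public fitting API ---------------------------------------------------

#' Fit the logistic decline model to one patient
#'
#' Minimises the sum of squared score residuals over `(d50, dx)` (and the
#' ceiling, if freed) with bound-constrained quasi-Newton least squares,
#' seeded by [initial_estimates()]. Every fit is assigned exactly one
#' status:
#'
#' * `converged` -- the optimiser succeeded and strictly improved on the
#'   seed;
#' * `degenerate_initial` -- the optimiser terminated at (epsilon-close
#'   to) the seed with no improvement. This is the characteristic stall
#'   of slow progressors under paper-mode seeding: the seed describes a
#'   near-step curve whose plateau spans all visits, so the objective has
#'   no usable gradient and the "optimal" values simply echo the seeds;
#' * `boundary` -- a parameter finished on a search bound;
#' * `failed` -- anything else (including unusable zero-slope seeds).
#'
#' @param trajectory An [als_trajectory()] with at least three visits.
#' @param config A [fit_config()].
#' @return An object of class `als_fit`: fitted `params`
#'   ([logistic_params()] or `NULL` when no usable fit exists), the
#'   `initials`, `status`, `reason`, `sse`, `sse_init`, `n_iterations`,
#'   per-visit `predicted` scores, and empty CI slots filled by
#'   [bootstrap_ci()].
#' @export
fit_patient <- function(trajectory, config) {
  check_trajectory(trajectory)
  check_config(config)
  if (!is_eligible(trajectory)) {
    stop_d50(sprintf("patient %s has %d visits; fitting requires at least three successive total scores",
                     trajectory$patient_id, n_visits(trajectory)), "eligibility")
  }
  inits <- initial_estimates(trajectory, method = config$init_method,
                             mode = config$init_mode)
  x <- trajectory$months
  y <- trajectory$scores

  if (inits$zero_slope) {
    return(new_als_fit(trajectory, config, inits, params = NULL,
                       status = "failed", reason = "zero or negative conventional slope",
                       sse = NA_real_, sse_init = NA_real_, n_iterations = 0L,
                       predicted = rep(NA_real_, length(x))))
  }

  ymax_mode <- if (!config$constrain_ymax) "free"
               else if (config$fix_ymax_at_48) "fixed" else "bounded"
  res <- .fit_xy(x, y, inits, config, ymax_mode)
  p <- .theta_unpack(res)
  params <- if (res$ok && p$y_max > 0 && p$d50 > 0 && p$dx > 0) {
    logistic_params(d50 = p$d50, dx = p$dx, y_max = p$y_max)
  } else NULL
  predicted <- .logistic(x, p$y_max, p$d50, p$dx)
  new_als_fit(trajectory, config, inits, params = params,
              status = res$status, reason = res$reason,
              sse = res$sse, sse_init = res$sse_init,
              n_iterations = res$n_iterations, predicted = predicted)
}

new_als_fit <- function(trajectory, config, inits, params, status, reason,
                        sse, sse_init, n_iterations, predicted) {
  structure(list(patient_id = trajectory$patient_id,
                 params = params,
                 initials = inits,
                 status = status,
                 reason = reason,
                 sse = sse,
                 sse_init = sse_init,
                 n_iterations = n_iterations,
                 months = trajectory$months,
                 observed = trajectory$scores,
                 predicted = predicted,
                 ci_d50 = NULL,
                 ci_dx = NULL,
                 ci_level = NULL,
                 bootstrap = NULL,
                 seed = config$seed,
                 init_mode = config$init_mode),
            class = "als_fit")
}

#' @export
print.als_fit <- function(x, ...) {
  cat(sprintf("<als_fit> patient %s: status %s", x$patient_id, x$status))
  if (!is.null(x$params)) {
    cat(sprintf(", D50 = %.3f, dx = %.3f, SSE = %.4g", x$params$d50, x$params$dx, x$sse))
  }
  if (!is.null(x$ci_d50)) {
    cat(sprintf("\n  %g%% bootstrap CI: D50 [%.3f, %.3f], dx [%.3f, %.3f]",
                100 * x$ci_level, x$ci_d50[1], x$ci_d50[2], x$ci_dx[1], x$ci_dx[2]))
  }
  cat("\n")
  invisible(x)
}

#' Case-resampling bootstrap confidence intervals for D50 and dx
#'
#' Resamples visits with replacement (redrawing any replicate with fewer
#' than three distinct visit times), re-seeds and refits each replicate,
#' and returns percentile intervals at `config$ci_level`. Deterministic
#' for a fixed `config$seed`. Replicates whose refit does not converge
#' are dropped; if more than half fail, the result carries a
#' `wide_interval` warning flag (the interval is still reported).
#'
#' @inheritParams fit_patient
#' @param fit Optional pre-computed converged [fit_patient()] result for
#'   this trajectory (recomputed if omitted).
#' @return A list of class `bootstrap_ci`: `ci_d50`, `ci_dx`, `level`,
#'   `n_bootstrap`, `n_failed`, `wide_interval`.
#' @export
bootstrap_ci <- function(trajectory, config, fit = NULL) {
  check_trajectory(trajectory)
  check_config(config)
  if (is.null(fit)) fit <- fit_patient(trajectory, config)
  if (fit$status != "converged") {
    stop_d50(sprintf("bootstrap requires a converged base fit (patient %s has status '%s')",
                     trajectory$patient_id, fit$status), "validation")
  }
  x <- trajectory$months
  y <- trajectory$scores
  n <- length(x)
  ymax_mode <- if (!config$constrain_ymax) "free"
               else if (config$fix_ymax_at_48) "fixed" else "bounded"

  draws_d50 <- numeric(0)
  draws_dx <- numeric(0)
  n_failed <- 0L
  withr::with_seed(config$seed, {
    for (b in seq_len(config$n_bootstrap)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(x[idx])) >= 3L) break
      }
      ord <- order(x[idx])
      xb <- x[idx][ord]
      yb <- y[idx][ord]
      slope <- .conv_slope_xy(xb, yb)
      if (!is.finite(slope) || slope <= 0) {
        n_failed <- n_failed + 1L
        next
      }
      ib <- list(init_d50 = .init_d50_xy(xb, yb, slope),
                 init_dx = .init_dx_xy(slope, config$init_mode))
      res <- .fit_xy(xb, yb, ib, config, ymax_mode)
      if (res$ok && res$status %in% c("converged", "degenerate_initial")) {
        p <- .theta_unpack(res)
        draws_d50 <- c(draws_d50, p$d50)
        draws_dx <- c(draws_dx, p$dx)
      } else {
        n_failed <- n_failed + 1L
      }
    }
  })

  if (length(draws_d50) < 2L) {
    stop_d50(sprintf("bootstrap produced %d usable replicate(s) of %d; cannot form an interval",
                     length(draws_d50), config$n_bootstrap), "bootstrap")
  }
  alpha <- 1 - config$ci_level
  probs <- c(alpha / 2, 1 - alpha / 2)
  structure(list(ci_d50 = unname(stats::quantile(draws_d50, probs)),
                 ci_dx = unname(stats::quantile(draws_dx, probs)),
                 level = config$ci_level,
                 n_bootstrap = config$n_bootstrap,
                 n_failed = n_failed,
                 wide_interval = n_failed > config$n_bootstrap / 2),
            class = "bootstrap_ci")
}

#' Attach bootstrap intervals to a fit
#'
#' Convenience wrapper running [bootstrap_ci()] and storing the intervals
#' in the `als_fit` object.
#'
#' @inheritParams bootstrap_ci
#' @param fit A converged [fit_patient()] result.
#' @return The fit with `ci_d50`, `ci_dx`, `ci_level` and `bootstrap`
#'   filled in.
#' @export
add_bootstrap_ci <- function(fit, trajectory, config) {
  ci <- bootstrap_ci(trajectory, config, fit)
  fit$ci_d50 <- ci$ci_d50
  fit$ci_dx <- ci$ci_dx
  fit$ci_level <- ci$level
  fit$bootstrap <- ci
  fit
}

#' Diagnostic refit without the ceiling constraint
#'
#' Refits the patient with the curve ceiling left completely free (only
#' `d50` and `dx` keep their search bounds) while still seeding the
#' ceiling at 48, then evaluates the fitted curve on a fine grid across
#' the observation span and reports whether any prediction exceeds 48 or
#' falls below zero. Such out-of-range fits demonstrate why the ceiling
#' is constrained in normal use.
#'
#' @inheritParams fit_patient
#' @param n_grid Number of evaluation points across the observation span.
#' @return A list of class `unconstrained_diagnostic`: the unconstrained
#'   parameter estimates (`y_max`, `d50`, `dx`), fit `status`, `sse`,
#'   the prediction range over the span, and logical `out_of_range`.
#' @export
diagnose_unconstrained <- function(trajectory, config, n_grid = 201L) {
  check_trajectory(trajectory)
  check_config(config)
  if (!is_eligible(trajectory)) {
    stop_d50(sprintf("patient %s has %d visits; fitting requires at least three successive total scores",
                     trajectory$patient_id, n_visits(trajectory)), "eligibility")
  }
  inits <- initial_estimates(trajectory, method = config$init_method,
                             mode = config$init_mode)
  if (inits$zero_slope) {
    stop_d50("zero or negative conventional slope: no usable seed for the diagnostic refit",
             "zero_slope")
  }
  x <- trajectory$months
  y <- trajectory$scores
  res <- .fit_xy(x, y, inits, config, ymax_mode = "free")
  p <- .theta_unpack(res)
  grid <- seq(min(x), max(x), length.out = n_grid)
  pred <- .logistic(grid, p$y_max, p$d50, p$dx)
  rng <- range(pred)
  structure(list(patient_id = trajectory$patient_id,
                 y_max = p$y_max, d50 = p$d50, dx = p$dx,
                 status = res$status, sse = res$sse,
                 prediction_range = rng,
                 out_of_range = rng[2] > 48 + 1e-9 || rng[1] < -1e-9),
            class = "unconstrained_diagnostic")
}

#' @export
print.unconstrained_diagnostic <- function(x, ...) {
  cat(sprintf("<unconstrained_diagnostic> patient %s: ceiling estimate %.2f, predictions span [%.2f, %.2f] -> %s\n",
              x$patient_id, x$y_max, x$prediction_range[1], x$prediction_range[2],
              if (x$out_of_range) "OUT OF RANGE" else "within [0, 48]"))
  invisible(x)
}

#' Fit every eligible patient in a cohort
#'
#' Applies [fit_patient()] patient by patient. Patients with fewer than
#' three visits are reported with status `ineligible` rather than
#' aborting the cohort; zero-slope patients come back as `failed`.
#'
#' @param cohort An [als_cohort()].
#' @param config A [fit_config()].
#' @param bootstrap Also compute bootstrap intervals for every converged
#'   fit (can be slow for large `n_bootstrap`).
#' @return A named list of `als_fit` objects with class `als_fit_list`.
#' @export
fit_cohort <- function(cohort, config, bootstrap = FALSE) {
  if (!inherits(cohort, "als_cohort")) stop_d50("expected an `als_cohort`", "validation")
  check_config(config)
  fits <- lapply(unclass(cohort), function(tr) {
    if (!is_eligible(tr)) {
      inits <- structure(list(conventional_slope = NA_real_, init_dx = NA_real_,
                              init_d50 = NA_real_, method = config$init_method,
                              mode = config$init_mode, zero_slope = FALSE),
                         class = "initial_estimates")
      return(new_als_fit(tr, config, inits, params = NULL,
                         status = "ineligible",
                         reason = sprintf("%d visit(s); at least three required", n_visits(tr)),
                         sse = NA_real_, sse_init = NA_real_, n_iterations = 0L,
                         predicted = rep(NA_real_, n_visits(tr))))
    }
    fit <- fit_patient(tr, config)
    if (bootstrap && fit$status == "converged") {
      fit <- add_bootstrap_ci(fit, tr, config)
    }
    fit
  })
  structure(fits, class = "als_fit_list")
}

#' @export
print.als_fit_list <- function(x, ...) {
  st <- table(vapply(x, function(f) f$status, character(1)))
  cat(sprintf("<als_fit_list> %d patients: %s\n", length(x),
              paste(sprintf("%s %d", names(st), st), collapse = ", ")))
  invisible(x)
}

#' Tabulate per-patient fit results
#'
#' @param fits An `als_fit_list` from [fit_cohort()] (or a list of
#'   `als_fit` objects).
#' @return A `data.frame` with one row per patient: identifiers, status,
#'   conventional slope, seed values, optimal values, SSE and CI bounds.
#' @export
fit_results_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    data.frame(patient_id = f$patient_id,
               status = f$status,
               conventional_slope = f$initials$conventional_slope,
               init_dx = f$initials$init_dx,
               init_d50 = f$initials$init_d50,
               d50 = if (!is.null(f$params)) f$params$d50 else NA_real_,
               dx = if (!is.null(f$params)) f$params$dx else NA_real_,
               y_max = if (!is.null(f$params)) f$params$y_max else NA_real_,
               sse = f$sse,
               n_iterations = f$n_iterations,
               ci_d50_lo = if (!is.null(f$ci_d50)) f$ci_d50[1] else NA_real_,
               ci_d50_hi = if (!is.null(f$ci_d50)) f$ci_d50[2] else NA_real_,
               ci_dx_lo = if (!is.null(f$ci_dx)) f$ci_dx[1] else NA_real_,
               ci_dx_hi = if (!is.null(f$ci_dx)) f$ci_dx[2] else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialise fit results
#'
#' `write_fit_results()` writes the one-row-per-patient CSV of
#' [fit_results_table()]; `write_fit_report()` writes a JSON report
#' preserving full numeric precision, including per-visit observed and
#' predicted scores.
#'
#' @inheritParams fit_results_table
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_fit_results <- function(fits, path) {
  utils::write.csv(fit_results_table(fits), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fit_results
#' @export
write_fit_report <- function(fits, path) {
  report <- lapply(fits, function(f) {
    list(patient_id = f$patient_id,
         status = f$status,
         init_mode = f$init_mode,
         seed = f$seed,
         initials = f$initials[c("conventional_slope", "init_dx", "init_d50")],
         params = if (!is.null(f$params)) f$params[c("y_max", "d50", "dx")] else NULL,
         sse = f$sse,
         months = f$months,
         observed = f$observed,
         predicted = f$predicted,
         ci_d50 = f$ci_d50,
         ci_dx = f$ci_dx,
         ci_level = f$ci_level)
  })
  jsonlite::write_json(unname(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
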