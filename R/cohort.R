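#' Classify a patient as slow or fast progressor
#'
#' Applies the conventional-slope threshold of 0.365 points/month (the
#' slow-progressor definition of Poesen and colleagues): strictly below
#' the threshold is `slow`, the boundary value itself and anything above
#' is `fast`. The threshold applies to the conventional linear decline
#' rate, *not* to the fitted steepness denominator `dx` -- the two share
#' a symbol in clinical shorthand but have different units.
#'
#' @param conventional_slope Positive decline rate(s) in points/month
#'   (vectorised).
#' @return Character vector of `"slow"` / `"fast"`.
#' @export
classify_progressor <- function(conventional_slope) {
  if (!is.numeric(conventional_slope) || length(conventional_slope) == 0L ||
      any(!is.finite(conventional_slope))) {
    stop_d50("`conventional_slope` must be finite", "validation")
  }
  if (any(conventional_slope <= 0)) {
    stop_d50("progressor classification requires a positive decline rate", "validation")
  }
  ifelse(conventional_slope < 0.365, "slow", "fast")
}

#' Descriptive statistics of seed and optimal parameters by fit outcome
#'
#' Reproduces the layout of per-group parameter tables: for the converged
#' and the non-converged patients separately, `n`, minimum, maximum,
#' mean, and sample (n-1 denominator) standard deviation of the seed and
#' optimal values of `dx` and `D50`. For degenerate fits the optimal
#' values echo the seeds, so the non-converged group's seed and optimal
#' rows coincide. `sd` is reported as `NA` (undefined), not 0, when a
#' group holds a single value.
#'
#' @param fits An `als_fit_list` from [fit_cohort()], or the data frame
#'   of [fit_results_table()].
#' @return A `data.frame` with columns `group`, `quantity`, `n`,
#'   `minimum`, `maximum`, `mean`, `sd`.
#' @export
summarize_cohort <- function(fits) {
  tab <- if (is.data.frame(fits)) fits else fit_results_table(fits)
  if (nrow(tab) == 0L) stop_d50("no fit results to summarise", "validation")
  tab$group <- ifelse(tab$status == "converged", "converged", "not_converged")
  quantities <- c(init_dx = "initial dx", dx = "optimal dx",
                  init_d50 = "initial D50", d50 = "optimal D50")
  rows <- list()
  for (g in c("converged", "not_converged")) {
    sub <- tab[tab$group == g, , drop = FALSE]
    for (col in names(quantities)) {
      v <- sub[[col]]
      v <- v[is.finite(v)]
      n <- length(v)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g,
        quantity = unname(quantities[col]),
        n = n,
        minimum = if (n > 0) min(v) else NA_real_,
        maximum = if (n > 0) max(v) else NA_real_,
        mean = if (n > 0) mean(v) else NA_real_,
        sd = if (n > 1) stats::sd(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Mean squares of the two-way (subject x rater) layout with k raters,
## the building blocks of the absolute-agreement ICC.
.two_way_ms <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  list(n = n, k = k,
       msr = ss_rows / (n - 1),
       msc = ss_cols / (k - 1),
       mse = ss_err / ((n - 1) * (k - 1)))
}

#' Agreement between observed and model-predicted scores
#'
#' Quantifies absolute agreement between paired score series with three
#' standard statistics:
#'
#' * `r_squared` -- squared Pearson correlation (consistency only: a
#'   constant offset still gives 1);
#' * `icc` -- intraclass correlation, two-way mixed, absolute-agreement,
#'   single-measures form (ICC(A,1) of McGraw & Wong), with its
#'   large-sample F-based confidence interval. A constant offset between
#'   the series *lowers* this one;
#' * `cronbach_alpha` -- internal-consistency alpha over the two series.
#'
#' If either series has zero variance the agreement statistics are
#' undefined; the report then carries `degenerate = TRUE` with `NA`
#' metrics rather than an arbitrary number.
#'
#' @param observed,predicted Equal-length numeric vectors, n >= 3.
#' @param ci_level Confidence level for the ICC interval.
#' @return A list of class `agreement_report`: `r_squared`, `icc`,
#'   `icc_ci`, `cronbach_alpha`, `n_pairs`, `degenerate`.
#' @export
agreement <- function(observed, predicted, ci_level = 0.95) {
  if (!is.numeric(observed) || !is.numeric(predicted) ||
      length(observed) != length(predicted)) {
    stop_d50("`observed` and `predicted` must be equal-length numeric vectors", "validation")
  }
  if (length(observed) < 3L) stop_d50("agreement needs at least 3 pairs", "validation")
  if (anyNA(observed) || anyNA(predicted)) {
    stop_d50("agreement inputs must not contain missing values", "validation")
  }
  n <- length(observed)
  if (stats::var(observed) == 0 || stats::var(predicted) == 0) {
    return(structure(list(r_squared = NA_real_, icc = NA_real_,
                          icc_ci = c(NA_real_, NA_real_),
                          cronbach_alpha = NA_real_, n_pairs = n,
                          degenerate = TRUE),
                     class = "agreement_report"))
  }
  r2 <- stats::cor(observed, predicted)^2

  mat <- cbind(observed, predicted)
  ms <- .two_way_ms(mat)
  k <- ms$k
  icc <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))

  alpha_level <- 1 - ci_level
  if (icc >= 1 - 1e-12) {
    ci <- c(icc, icc)   # perfect agreement: no residual variance to bound
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha_level / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha_level / 2, v, n - 1)
    lower <- n * (ms$msr - f_l * ms$mse) /
      (f_l * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    upper <- n * (f_u * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * f_u * ms$msr)
    ci <- c(lower, upper)
  }

  v1 <- stats::var(observed); v2 <- stats::var(predicted)
  vt <- stats::var(observed + predicted)
  cronbach <- (k / (k - 1)) * (1 - (v1 + v2) / vt)

  structure(list(r_squared = r2, icc = icc, icc_ci = ci,
                 cronbach_alpha = cronbach, n_pairs = n, degenerate = FALSE),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<agreement_report> %d pairs: degenerate (zero variance)\n", x$n_pairs))
  } else {
    cat(sprintf("<agreement_report> %d pairs: R^2 = %.4f, ICC(A,1) = %.4f [%.4f, %.4f], alpha = %.4f\n",
                x$n_pairs, x$r_squared, x$icc, x$icc_ci[1], x$icc_ci[2], x$cronbach_alpha))
  }
  invisible(x)
}

#' Ordinary least-squares relationship between two parameter series
#'
#' Simple linear regression used for cohort-level parameter
#' relationships, e.g. fitted steepness versus midpoint time, or
#' conventionally seeded versus optimised D50.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, `x` non-constant.
#' @return A list of class `parameter_relation`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
relate_parameters <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop_d50("`x` and `y` must be equal-length numeric vectors", "validation")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop_d50("regression needs at least 3 complete pairs", "validation")
  if (stats::var(x) == 0) stop_d50("`x` has zero variance; no regression line exists", "validation")
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n = length(x)),
            class = "parameter_relation")
}

#' @export
print.parameter_relation <- function(x, ...) {
  cat(sprintf("<parameter_relation> n = %d: y = %.4g + %.4g x, R^2 = %.4f\n",
              x$n, x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Write an agreement or regression report as JSON
#'
#' @param report An `agreement_report` or `parameter_relation`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (!inherits(report, c("agreement_report", "parameter_relation"))) {
    stop_d50("expected an agreement_report or parameter_relation", "validation")
  }
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
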