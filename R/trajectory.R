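#' Sum ALSFRS-R item sub-scores into a total score
#'
#' The revised ALS Functional Rating Scale has 12 items, each scored 0-4,
#' so totals range from 0 (maximum disability) to 48 (normal function).
#' All 12 items are required; missing sub-scores are an error rather than
#' being imputed.
#'
#' @param item_scores Numeric vector of exactly 12 integer item scores,
#'   each in 0-4, no missing values.
#' @return Integer total in `[0, 48]`.
#' @examples
#' sum_subscores(rep(4, 12))  # 48
#' @export
sum_subscores <- function(item_scores) {
  if (length(item_scores) != 12L) {
    stop_d50(sprintf("expected 12 item scores, got %d", length(item_scores)),
             "validation")
  }
  if (anyNA(item_scores)) {
    stop_d50("missing item sub-score: all 12 items are required", "missing_data")
  }
  if (!is.numeric(item_scores) || any(item_scores != trunc(item_scores)) ||
      any(item_scores < 0) || any(item_scores > 4)) {
    stop_d50("item scores must be integers in [0, 4]", "validation")
  }
  as.integer(sum(item_scores))
}

#' Construct a single-patient ALSFRS-R trajectory
#'
#' One patient's clinic-visit history: months since symptom onset paired
#' with total ALSFRS-R scores, rearranged into increasing chronological
#' order. Scores need not decline monotonically -- transient gains between
#' visits are valid clinical data (e.g. after an intervention) -- but
#' duplicate visit times are rejected as probable entry errors, never
#' averaged.
#'
#' @param patient_id Opaque identifier string.
#' @param months Visit times in decimal months since onset, all positive.
#'   Rows are reordered chronologically; order of the input is irrelevant.
#' @param scores Total ALSFRS-R scores in `[0, 48]`, one per visit.
#' @param onset_age Age at symptom onset in years, or `NA`.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param onset_site `"bulbar"`, `"lower_limb"`, `"upper_limb"` or
#'   `"unknown"`.
#' @return An object of class `als_trajectory`.
#' @export
als_trajectory <- function(patient_id, months, scores, onset_age = NA_real_,
                           sex = "unknown", onset_site = "unknown") {
  if (!is.character(patient_id) || length(patient_id) != 1L || is.na(patient_id) ||
      !nzchar(patient_id)) {
    stop_d50("`patient_id` must be a non-empty string", "validation")
  }
  if (length(months) != length(scores)) {
    stop_d50("`months` and `scores` must have equal length", "validation")
  }
  if (length(months) == 0L) stop_d50("a trajectory needs at least one visit", "validation")
  if (!is.numeric(months) || anyNA(months) || any(!is.finite(months))) {
    stop_d50("`months` must be finite numbers", "validation")
  }
  if (any(months <= 0)) {
    stop_d50("months since onset must be positive", "validation")
  }
  if (!is.numeric(scores) || anyNA(scores) || any(!is.finite(scores))) {
    stop_d50("`scores` must be finite numbers", "validation")
  }
  if (any(scores < 0) || any(scores > 48)) {
    stop_d50("total ALSFRS-R scores must lie in [0, 48]", "validation")
  }
  if (anyDuplicated(months)) {
    stop_d50(sprintf("patient %s has duplicate visit times; duplicate (patient, time) rows are entry errors, not repeats to average",
                     patient_id), "duplicate")
  }
  sex <- match.arg(sex, c("male", "female", "unknown"))
  onset_site <- match.arg(onset_site, c("bulbar", "lower_limb", "upper_limb", "unknown"))
  ord <- order(months)
  structure(
    list(patient_id = patient_id,
         months = as.numeric(months[ord]),
         scores = as.numeric(scores[ord]),
         onset_age = as.numeric(onset_age),
         sex = sex,
         onset_site = onset_site),
    class = "als_trajectory"
  )
}

#' @export
print.als_trajectory <- function(x, ...) {
  cat(sprintf("<als_trajectory> patient %s: %d visits, months %.1f-%.1f, scores %g -> %g\n",
              x$patient_id, n_visits(x), x$months[1], x$months[n_visits(x)],
              x$scores[1], x$scores[n_visits(x)]))
  invisible(x)
}

#' Number of visits in a trajectory
#' @param trajectory An [als_trajectory()].
#' @return Integer visit count.
#' @export
n_visits <- function(trajectory) {
  check_trajectory(trajectory)
  length(trajectory$months)
}

#' Is a trajectory eligible for model fitting?
#'
#' Fitting requires at least three successive total scores.
#' @inheritParams n_visits
#' @return Logical scalar.
#' @export
is_eligible <- function(trajectory) n_visits(trajectory) >= 3L

check_trajectory <- function(trajectory) {
  if (!inherits(trajectory, "als_trajectory")) {
    stop_d50("expected an `als_trajectory` object", "validation")
  }
  invisible(trajectory)
}

#' Construct a cohort of patient trajectories
#'
#' @param trajectories List of [als_trajectory()] objects with distinct
#'   patient identifiers.
#' @return An object of class `als_cohort` (a named list of trajectories).
#' @export
als_cohort <- function(trajectories = list()) {
  if (!is.list(trajectories)) stop_d50("`trajectories` must be a list", "validation")
  for (tr in trajectories) check_trajectory(tr)
  ids <- vapply(trajectories, function(tr) tr$patient_id, character(1))
  if (anyDuplicated(ids)) {
    stop_d50("duplicate patient identifiers in cohort", "duplicate")
  }
  structure(stats::setNames(trajectories, ids), class = "als_cohort")
}

#' @export
print.als_cohort <- function(x, ...) {
  nv <- vapply(x, n_visits, integer(1))
  cat(sprintf("<als_cohort> %d patients, %d visits (%s eligible for fitting)\n",
              length(x), sum(nv), sum(nv >= 3L)))
  invisible(x)
}

#' @export
`[.als_cohort` <- function(x, i) {
  als_cohort(unclass(x)[i])
}

#' Flatten a cohort to a long-format data frame
#'
#' One row per visit, with per-patient demographics repeated on each row.
#' This is also the on-disk CSV layout used by [write_cohort()].
#'
#' @param x An [als_cohort()].
#' @param row.names,optional,... Ignored; present for S3 compatibility.
#' @return A `data.frame` with columns `patient_id`, `months_since_onset`,
#'   `total_score`, `onset_age`, `sex`, `onset_site`.
#' @export
as.data.frame.als_cohort <- function(x, row.names = NULL, optional = FALSE, ...) {
  if (length(x) == 0L) {
    return(data.frame(patient_id = character(), months_since_onset = numeric(),
                      total_score = numeric(), onset_age = numeric(),
                      sex = character(), onset_site = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(unclass(x), function(tr) {
    data.frame(patient_id = tr$patient_id,
               months_since_onset = tr$months,
               total_score = tr$scores,
               onset_age = tr$onset_age,
               sex = tr$sex,
               onset_site = tr$onset_site,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.cohort_columns <- c("patient_id", "months_since_onset", "total_score",
                     "onset_age", "sex", "onset_site")
.item_columns <- paste0("item_", 1:12)

.resolve_dialect <- function(dialect) {
  if (is.null(dialect)) return(list())
  if (is.character(dialect) && length(dialect) == 1L) {
    dialect <- yaml::read_yaml(dialect)
  }
  if (!is.list(dialect)) {
    stop_d50("`dialect` must be a named list or path to a YAML file", "validation")
  }
  dialect
}

#' Read a longitudinal ALSFRS-R cohort from CSV
#'
#' Expects long-format data with columns `patient_id`,
#' `months_since_onset`, and either `total_score` or the 12 item columns
#' `item_1` ... `item_12` (summed via [sum_subscores()]). When both totals
#' and items are present they must agree row by row. Visits are reordered
#' chronologically per patient; all range and uniqueness invariants are
#' enforced, never silently repaired. Optional demographic columns
#' `onset_age`, `sex`, `onset_site` are carried through.
#'
#' @param path CSV file path (UTF-8, RFC-4180 quoting).
#' @param dialect Optional column-name remapping: a named list (or path to
#'   a YAML file containing one) whose names are the canonical column
#'   names above and whose values are the names used in the file, e.g.
#'   `list(patient_id = "id", months_since_onset = "time_m")`.
#' @return An [als_cohort()].
#' @export
read_cohort <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop_d50(sprintf("file not found: %s", path), "io")
  dialect <- .resolve_dialect(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (canonical in names(dialect)) {
    idx <- match(dialect[[canonical]], names(df))
    if (!is.na(idx)) names(df)[idx] <- canonical
  }
  required <- c("patient_id", "months_since_onset")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_d50(sprintf("missing required column(s): %s",
                     paste(missing_cols, collapse = ", ")), "format")
  }
  has_total <- "total_score" %in% names(df)
  has_items <- all(.item_columns %in% names(df))
  if (!has_total && !has_items) {
    stop_d50("need either a `total_score` column or all of item_1..item_12", "format")
  }
  if (nrow(df) == 0L) return(als_cohort(list()))

  df$patient_id <- as.character(df$patient_id)
  if (!is.numeric(df$months_since_onset)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$months_since_onset))))
    stop_d50(sprintf("unparseable months_since_onset at data row(s): %s",
                     paste(utils::head(bad, 5), collapse = ", ")), "format")
  }
  if (anyNA(df$months_since_onset) || anyNA(df$patient_id)) {
    bad <- which(is.na(df$months_since_onset) | is.na(df$patient_id))
    stop_d50(sprintf("missing identifier or visit time at data row(s): %s",
                     paste(utils::head(bad, 5), collapse = ", ")), "format")
  }

  if (has_items) {
    item_totals <- vapply(seq_len(nrow(df)), function(i) {
      items <- as.numeric(df[i, .item_columns])
      tryCatch(sum_subscores(items), d50fit_error = function(e) {
        stop_d50(sprintf("data row %d: %s", i, conditionMessage(e)),
                 "format")
      })
    }, numeric(1))
    if (has_total) {
      mism <- which(abs(as.numeric(df$total_score) - item_totals) > 1e-9)
      if (length(mism) > 0L) {
        stop_d50(sprintf("total_score disagrees with the item sum at data row(s): %s",
                         paste(utils::head(mism, 5), collapse = ", ")), "conflict")
      }
    }
    df$total_score <- item_totals
  }
  if (!is.numeric(df$total_score) || anyNA(df$total_score)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$total_score))))
    stop_d50(sprintf("unparseable or missing total_score at data row(s): %s",
                     paste(utils::head(bad, 5), collapse = ", ")), "format")
  }

  trajectories <- lapply(split(df, factor(df$patient_id, levels = unique(df$patient_id))),
                         function(sub) {
    first <- sub[1, ]
    als_trajectory(
      patient_id = first$patient_id,
      months = sub$months_since_onset,
      scores = sub$total_score,
      onset_age = if ("onset_age" %in% names(sub)) as.numeric(first$onset_age) else NA_real_,
      sex = if ("sex" %in% names(sub)) as.character(first$sex) else "unknown",
      onset_site = if ("onset_site" %in% names(sub)) as.character(first$onset_site) else "unknown"
    )
  })
  als_cohort(unname(trajectories))
}

#' Write a cohort to long-format CSV
#'
#' One row per visit with a stable column order
#' (`patient_id, months_since_onset, total_score, onset_age, sex,
#' onset_site`). Real-valued fields are written with full (17 significant
#' digit) precision so that [read_cohort()] round-trips exactly.
#'
#' @param cohort An [als_cohort()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (!inherits(cohort, "als_cohort")) stop_d50("expected an `als_cohort`", "validation")
  df <- as.data.frame(cohort)
  out <- data.frame(
    patient_id = df$patient_id,
    months_since_onset = sprintf("%.17g", df$months_since_onset),
    total_score = sprintf("%.17g", df$total_score),
    onset_age = ifelse(is.na(df$onset_age), "NA", sprintf("%.17g", df$onset_age)),
    sex = df$sex,
    onset_site = df$onset_site,
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_d50(sprintf("cannot write to %s", path), "io")
  invisible(path)
}
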