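test_that("sub-score summation enforces the 12-item 0-4 structure", {
  expect_equal(sum_subscores(rep(4, 12)), 48L)
  expect_equal(sum_subscores(rep(0, 12)), 0L)
  expect_equal(sum_subscores(c(4, 4, 4, 3, 3, 3, 2, 2, 2, 1, 1, 1)), 30L)
  expect_error(sum_subscores(rep(4, 11)), class = "d50fit_validation_error")
  expect_error(sum_subscores(c(rep(3, 11), NA)), class = "d50fit_missing_data_error")
  expect_error(sum_subscores(c(rep(3, 11), 5)), class = "d50fit_validation_error")
  expect_error(sum_subscores(c(rep(3, 11), 2.5)), class = "d50fit_validation_error")
})

test_that("trajectories are chronologically ordered and validated", {
  tr <- als_trajectory("A", months = c(30, 10, 20), scores = c(28, 44, 37))
  expect_equal(tr$months, c(10, 20, 30))
  expect_equal(tr$scores, c(44, 37, 28))
  # transient gains are valid clinical data
  expect_silent(als_trajectory("B", c(40, 44, 48), c(24, 22, 27)))
  expect_error(als_trajectory("C", c(10, 10, 20), c(40, 41, 30)),
               class = "d50fit_duplicate_error")
  expect_error(als_trajectory("D", c(-1, 5), c(40, 30)),
               class = "d50fit_validation_error")
  expect_error(als_trajectory("E", c(5, 10), c(40, 50)),
               class = "d50fit_validation_error")
  expect_error(als_trajectory("", 5, 40), class = "d50fit_validation_error")
})

test_that("eligibility requires at least three visits", {
  expect_false(is_eligible(als_trajectory("A", c(5, 10), c(40, 30))))
  expect_true(is_eligible(als_trajectory("A", c(5, 10, 15), c(40, 30, 25))))
})

write_rows <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

test_that("read_cohort sorts visits, applies validation and reports rows", {
  path <- write_rows(c(
    "patient_id,months_since_onset,total_score",
    "p1,30,28", "p1,10,44", "p1,20,37"))
  co <- read_cohort(path)
  expect_equal(co[["p1"]]$months, c(10, 20, 30))
  expect_equal(co[["p1"]]$scores, c(44, 37, 28))

  bad <- write_rows(c("patient_id,months_since_onset,total_score", "p1,10,50"))
  expect_error(read_cohort(bad), class = "d50fit_validation_error")

  dup <- write_rows(c("patient_id,months_since_onset,total_score",
                      "p1,10,40", "p1,10,39"))
  expect_error(read_cohort(dup), class = "d50fit_duplicate_error")

  nocol <- write_rows(c("patient,months,score", "p1,10,40"))
  expect_error(read_cohort(nocol), class = "d50fit_format_error")

  gap <- write_rows(c("patient_id,months_since_onset,total_score",
                      "p1,10,40", "p1,,39"))
  expect_error(read_cohort(gap), "row", class = "d50fit_format_error")
})

test_that("item columns are summed and checked against provided totals", {
  items40 <- paste(c(4, 4, 4, 3, 3, 3, 4, 4, 4, 3, 2, 2), collapse = ",")
  path <- write_rows(c(
    paste(c("patient_id,months_since_onset", paste0("item_", 1:12)), collapse = ","),
    paste("p1,10", items40, sep = ","),
    paste("p1,20", items40, sep = ",")))
  co <- read_cohort(path)
  expect_equal(co[["p1"]]$scores, c(40, 40))

  conflicting <- write_rows(c(
    paste(c("patient_id,months_since_onset,total_score", paste0("item_", 1:12)),
          collapse = ","),
    paste("p1,10,39", items40, sep = ",")))
  expect_error(read_cohort(conflicting), class = "d50fit_conflict_error")

  consistent <- write_rows(c(
    paste(c("patient_id,months_since_onset,total_score", paste0("item_", 1:12)),
          collapse = ","),
    paste("p1,10,40", items40, sep = ",")))
  expect_silent(read_cohort(consistent))
})

test_that("a dialect can remap column names, including from YAML", {
  path <- write_rows(c("id,visit_month,frs_total", "p1,10,40", "p1,20,31", "p1,30,24"))
  dialect <- list(patient_id = "id", months_since_onset = "visit_month",
                  total_score = "frs_total")
  co <- read_cohort(path, dialect)
  expect_equal(co[["p1"]]$scores, c(40, 31, 24))

  ypath <- tempfile(fileext = ".yaml")
  writeLines(c("patient_id: id", "months_since_onset: visit_month",
               "total_score: frs_total"), ypath)
  co2 <- read_cohort(path, ypath)
  expect_equal(co2, co)
})

test_that("write/read round-trips cohorts exactly, including fractional months", {
  for (s in 1:5) {
    sim <- simulate_cohort(sim_config(seed = s, n_patients = 6))
    path <- tempfile(fileext = ".csv")
    write_cohort(sim$cohort, path)
    expect_equal(read_cohort(path), sim$cohort, tolerance = 0)
  }
})

test_that("empty and small cohorts serialise with expected shape", {
  path <- tempfile(fileext = ".csv")
  write_cohort(als_cohort(list()), path)
  expect_equal(length(readLines(path)), 1L)   # header only
  expect_equal(length(read_cohort(path)), 0L)

  co <- als_cohort(list(
    als_trajectory("a", c(5, 10, 15), c(44, 40, 36)),
    als_trajectory("b", c(6, 12, 18), c(42, 35, 28))))
  write_cohort(co, path)
  expect_equal(length(readLines(path)), 7L)   # header + 2 patients x 3 visits
  expect_error(write_cohort(co, file.path(tempdir(), "no/such/dir/x.csv")),
               class = "d50fit_io_error")
})
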