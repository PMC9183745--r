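test_that("noise-free trajectories recover their generating parameters", {
  tr <- fast_trajectory(d50 = 30, dx = 8)
  for (mode in c("converted", "paper")) {
    f <- fit_patient(tr, quiet_cfg(init_mode = mode))
    expect_equal(f$status, "converged")
    expect_equal(f$params$d50, 30, tolerance = 1e-6)
    expect_equal(f$params$dx, 8, tolerance = 1e-6)
    expect_lt(f$sse, 1e-12)
    expect_equal(length(f$predicted), n_visits(tr))
  }
})

test_that("fitted SSE never exceeds the brute-force grid minimum", {
  set.seed(33)
  cfg <- quiet_cfg()
  d50_grid <- 1:120
  dx_grid <- seq(0.5, 60, by = 0.5)
  n_checked <- 0
  for (i in 1:5) {
    d50 <- runif(1, 14, 40); dx <- runif(1, 4, 12)
    tr <- simulate_trajectory(logistic_params(d50 = d50, dx = dx),
                              seq(6, 46, by = 5), noise_sd = 2,
                              integerize = TRUE, patient_id = "G")
    f <- fit_patient(tr, cfg)
    if (f$status != "converged") next
    n_checked <- n_checked + 1
    best_grid <- oracle_grid_sse(tr$months, tr$scores, d50_grid, dx_grid)
    expect_lte(f$sse, best_grid + 1e-9)
  }
  expect_gte(n_checked, 4)
})

test_that("slow progressors stall at paper-mode seeds instead of silently converging", {
  cfg <- quiet_cfg(init_mode = "paper")
  for (s in 1:6) {
    tr <- slow_trajectory(seed = s)
    est <- initial_estimates(tr, mode = "paper")
    if (est$zero_slope) next
    f <- fit_patient(tr, cfg)
    expect_true(f$status %in% c("degenerate_initial", "boundary"))
    if (f$status == "degenerate_initial") {
      # the reported optimum echoes the seed, the published failure signature
      expect_equal(f$params$d50, f$initials$init_d50, tolerance = 1e-4)
      expect_equal(f$params$dx, f$initials$init_dx, tolerance = 1e-4)
      expect_gte(f$sse, f$sse_init - 1e-9)
    }
  }
})

test_that("every fit carries exactly one status and honours its contract", {
  set.seed(44)
  sim <- simulate_cohort(sim_config(seed = 44, n_patients = 12))
  fits <- fit_cohort(sim$cohort, quiet_cfg(init_mode = "paper"))
  statuses <- vapply(fits, function(f) f$status, character(1))
  expect_true(all(statuses %in% c("converged", "degenerate_initial",
                                  "boundary", "failed", "ineligible")))
  for (f in fits) {
    if (f$status == "converged") expect_lte(f$sse, f$sse_init)
    expect_equal(length(f$predicted), length(f$observed))
  }
})

test_that("ineligible and zero-slope patients are reported, not dropped", {
  two_visits <- als_trajectory("short", c(5, 10), c(40, 35))
  expect_error(fit_patient(two_visits, quiet_cfg()),
               class = "d50fit_eligibility_error")

  co <- als_cohort(list(
    two_visits,
    als_trajectory("flat", c(5, 10, 15), c(40, 40, 40)),
    fast_trajectory(id = "ok")))
  fits <- fit_cohort(co, quiet_cfg())
  tab <- fit_results_table(fits)
  expect_equal(tab$status[tab$patient_id == "short"], "ineligible")
  expect_equal(tab$status[tab$patient_id == "flat"], "failed")
  expect_equal(tab$status[tab$patient_id == "ok"], "converged")
})

test_that("constrained fits never predict outside the instrument range", {
  set.seed(55)
  for (i in 1:10) {
    d50 <- runif(1, 14, 60); dx <- runif(1, 2, 30)
    tr <- simulate_trajectory(logistic_params(d50 = d50, dx = dx),
                              sort(runif(7, 4, 60)), noise_sd = 3,
                              integerize = TRUE, patient_id = "R")
    f <- tryCatch(fit_patient(tr, quiet_cfg()), d50fit_error = function(e) NULL)
    if (is.null(f) || is.null(f$params)) next
    grid <- seq(min(tr$months), max(tr$months), length.out = 100)
    preds <- predict_score(f$params, grid)
    expect_true(all(preds >= 0 & preds <= 48))
  }
})

test_that("a general-purpose NLS solver finds no better optimum", {
  tr <- fast_trajectory(d50 = 26, dx = 6, visits = seq(5, 45, by = 5),
                        noise_sd = 2, integerize = TRUE, seed = 13)
  f <- fit_patient(tr, quiet_cfg())
  ref <- nls(scores ~ 48 / (1 + exp((months - d50) / dx)),
             data = data.frame(months = tr$months, scores = tr$scores),
             start = list(d50 = f$initials$init_d50, dx = f$initials$init_dx),
             algorithm = "port", lower = c(1e-6, 1e-3), upper = c(600, 200))
  expect_equal(f$sse, sum(residuals(ref)^2), tolerance = 1e-6)
})

test_that("bootstrap intervals are deterministic and collapse on noise-free data", {
  tr <- fast_trajectory()
  cfg <- quiet_cfg(seed = 9, n_bootstrap = 80)
  ci1 <- bootstrap_ci(tr, cfg)
  ci2 <- bootstrap_ci(tr, cfg)
  expect_identical(ci1, ci2)
  expect_lt(diff(ci1$ci_d50), 1e-6)
  expect_lt(diff(ci1$ci_dx), 1e-6)
  expect_false(ci1$wide_interval)

  other <- bootstrap_ci(tr, quiet_cfg(seed = 10, n_bootstrap = 80))
  expect_s3_class(other, "bootstrap_ci")

  slow <- slow_trajectory()
  expect_error(bootstrap_ci(slow, quiet_cfg(init_mode = "paper", n_bootstrap = 20)),
               class = "d50fit_validation_error")
})

test_that("bootstrap intervals cover the truth on noisy data", {
  # small-sample check; the full coverage study lives in the acceptance suite
  tr <- fast_trajectory(d50 = 28, dx = 7, visits = seq(8, 48, length.out = 9),
                        noise_sd = 2, integerize = TRUE, seed = 5)
  cfg <- quiet_cfg(seed = 17, n_bootstrap = 200)
  f <- fit_patient(tr, cfg)
  ci <- bootstrap_ci(tr, cfg, f)
  expect_true(ci$ci_d50[1] <= 28 && 28 <= ci$ci_d50[2])
  expect_true(ci$ci_d50[1] <= f$params$d50 && f$params$d50 <= ci$ci_d50[2])
})

test_that("unconstrained refits expose out-of-range predictions; constrained do not", {
  tr <- fast_trajectory(noise_sd = 2, integerize = TRUE, seed = 3)
  cfg <- quiet_cfg()
  d <- diagnose_unconstrained(tr, cfg)
  expect_false(d$out_of_range)

  # across simulated slow progressors, freeing the ceiling lets some fits
  # predict above 48 within the observation span
  cfgp <- quiet_cfg(init_mode = "paper")
  flagged <- 0L; ceilings <- numeric(0)
  for (s in 1:5) {
    sim <- simulate_cohort(sim_config(seed = s, slow_fraction = 1))
    for (tr_s in sim$cohort) {
      est <- initial_estimates(tr_s, mode = "paper")
      if (est$zero_slope) next
      ds <- diagnose_unconstrained(tr_s, cfgp)
      flagged <- flagged + ds$out_of_range
      ceilings <- c(ceilings, ds$y_max)
      fc <- fit_patient(tr_s, cfgp)
      expect_true(all(fc$predicted >= 0 & fc$predicted <= 48))
    }
  }
  expect_gte(flagged, 1L)
  expect_gt(max(ceilings), 48)   # fitted ceilings escape the instrument maximum
})

test_that("fit results serialise to CSV and JSON faithfully", {
  sim <- simulate_cohort(sim_config(seed = 3, n_patients = 5))
  fits <- fit_cohort(sim$cohort, quiet_cfg(n_bootstrap = 40), bootstrap = TRUE)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_fit_results(fits, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), 5)
  expect_true(all(c("patient_id", "status", "d50", "dx", "sse",
                    "ci_d50_lo", "ci_d50_hi") %in% names(back)))
  write_fit_report(fits, js)
  rep <- jsonlite::read_json(js)
  expect_equal(length(rep), 5)
  tab <- fit_results_table(fits)
  conv <- which(tab$status == "converged")[1]
  expect_equal(rep[[conv]]$params$d50, tab$d50[conv], tolerance = 1e-12)
})
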