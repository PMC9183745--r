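test_that("progressor classification applies the 0.365 points/month threshold", {
  expect_equal(classify_progressor(0.2117), "slow")
  expect_equal(classify_progressor(2.2002), "fast")
  expect_equal(classify_progressor(0.365), "fast")      # strict inequality
  expect_equal(classify_progressor(c(0.1, 0.5)), c("slow", "fast"))
  expect_error(classify_progressor(0), class = "d50fit_validation_error")
  expect_error(classify_progressor(-0.2), class = "d50fit_validation_error")
})

test_that("classified slow share tracks the generator's slow fraction", {
  sim <- simulate_cohort(sim_config(seed = 8, n_patients = 400))
  cls <- classify_progressor(sim$truth$true_slope)
  p_hat <- mean(cls == "slow")
  expect_lt(abs(p_hat - 0.35), 3 * sqrt(0.35 * 0.65 / 400))
  # by construction the true-slope classification recovers the hidden class
  expect_equal(cls, sim$truth$class)
})

test_that("cohort summaries reproduce hand-computed descriptive statistics", {
  tab <- data.frame(
    patient_id = c("a", "b", "c", "d"),
    status = c("converged", "converged", "converged", "degenerate_initial"),
    conventional_slope = c(1, 2, 3, 0.2),
    init_dx = c(1, 2, 3, 0.2),
    init_d50 = c(20, 30, 40, 150),
    d50 = c(22, 31, 38, 150),
    dx = c(5, 7, 9, 0.2),
    stringsAsFactors = FALSE)
  s <- summarize_cohort(tab)
  row <- s[s$group == "converged" & s$quantity == "initial dx", ]
  expect_equal(row$n, 3)
  expect_equal(row$minimum, 1)
  expect_equal(row$maximum, 3)
  expect_equal(row$mean, 2)
  expect_equal(row$sd, 1)   # sample sd of {1,2,3}

  nc <- s[s$group == "not_converged" & s$quantity == "optimal dx", ]
  expect_equal(nc$n, 1)
  expect_true(is.na(nc$sd))  # undefined for one value, never 0
  expect_equal(sum(s$n[s$quantity == "initial dx"]), 4)

  expect_error(summarize_cohort(tab[0, ]), class = "d50fit_validation_error")
})

test_that("summaries of a fitted synthetic cohort mirror the generator", {
  sim <- simulate_cohort(sim_config(seed = 42))
  fits <- fit_cohort(sim$cohort, quiet_cfg(init_mode = "paper"))
  s <- summarize_cohort(fits)
  conv_d50 <- s[s$group == "converged" & s$quantity == "optimal D50", ]
  fast_truth <- sim$truth$true_d50[sim$truth$class == "fast"]
  expect_equal(conv_d50$n, sum(sim$truth$class == "fast"))
  expect_lt(abs(conv_d50$mean - mean(fast_truth)), 3)
})

test_that("agreement metrics are exact on degenerate and shifted fixtures", {
  x <- c(44, 40, 35, 31, 26, 22)
  a <- agreement(x, x)
  expect_equal(a$r_squared, 1)
  expect_equal(a$icc, 1)
  expect_equal(a$cronbach_alpha, 1)

  shifted <- agreement(x, x + 5)
  expect_equal(shifted$r_squared, 1)     # consistency is perfect...
  expect_lt(shifted$icc, 1)              # ...absolute agreement is not

  flat <- agreement(rep(30, 5), c(31, 29, 30, 28, 32))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$icc))

  expect_error(agreement(1:2, 1:2), class = "d50fit_validation_error")
  expect_error(agreement(1:4, 1:5), class = "d50fit_validation_error")
})

test_that("agreement matches the two-way ANOVA formula oracle", {
  set.seed(61)
  obs <- c(46, 44, 41, 37, 33, 28, 24, 19, 15, 12)
  pred <- obs + rnorm(10, 0, 1.5)
  a <- agreement(obs, pred)

  expect_equal(a$r_squared, cor(obs, pred)^2, tolerance = 1e-12)

  # ICC(A,1) from aov-derived mean squares, transcribed independently
  n <- 10; k <- 2
  long <- data.frame(y = c(obs, pred),
                     subj = factor(rep(1:n, 2)),
                     rater = factor(rep(1:2, each = n)))
  ms <- anova(aov(y ~ subj + rater, data = long))
  msr <- ms["subj", "Mean Sq"]; msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  expect_equal(a$icc, icc_oracle, tolerance = 1e-9)

  # the F-based interval bounds, same route
  r <- icc_oracle
  aa <- (k * r) / (n * (1 - r)); bb <- 1 + (k * r * (n - 1)) / (n * (1 - r))
  v <- (aa * msc + bb * mse)^2 /
    ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(0.975, n - 1, v); fu <- qf(0.975, v, n - 1)
  lo <- n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr)
  expect_equal(a$icc_ci, c(lo, hi), tolerance = 1e-9)
  expect_true(a$icc_ci[1] < a$icc && a$icc < a$icc_ci[2])

  # Cronbach's alpha from its variance definition
  alpha_oracle <- (k / (k - 1)) * (1 - (var(obs) + var(pred)) / var(obs + pred))
  expect_equal(a$cronbach_alpha, alpha_oracle, tolerance = 1e-12)
})

test_that("parameter regressions equal the closed-form normal equations", {
  x <- c(1.2, 2.8, 4.1, 5.5, 7.3)
  y <- c(15.1, 24.8, 33.2, 41.9, 55.0)
  r <- relate_parameters(x, y)
  # normal equations long-hand
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y); n <- 5
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  expect_equal(r$slope, slope, tolerance = 1e-9)
  expect_equal(r$intercept, intercept, tolerance = 1e-9)
  expect_equal(r$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-9)
  expect_equal(r$r_squared, cor(x, y)^2, tolerance = 1e-12)

  collinear <- relate_parameters(1:5, 2 * (1:5) + 3)
  expect_equal(collinear$r_squared, 1)

  set.seed(71)
  shuffled <- relate_parameters(1:2000, sample(1:2000))
  expect_lt(shuffled$r_squared, 0.05)

  expect_error(relate_parameters(1:2, 1:2), class = "d50fit_validation_error")
  expect_error(relate_parameters(rep(2, 5), 1:5), class = "d50fit_validation_error")
})

test_that("noise-free model predictions agree perfectly with their source", {
  p <- logistic_params(d50 = 30, dx = 8)
  tr <- fast_trajectory()
  f <- fit_patient(tr, quiet_cfg())
  a <- agreement(tr$scores, f$predicted)
  expect_equal(a$r_squared, 1, tolerance = 1e-9)
  expect_equal(a$icc, 1, tolerance = 1e-9)
  expect_equal(a$cronbach_alpha, 1, tolerance = 1e-9)
})

test_that("agreement and regression reports serialise to JSON", {
  a <- agreement(c(40, 35, 30, 25), c(39, 36, 29, 26))
  path <- tempfile(fileext = ".json")
  write_report_json(a, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$r_squared, a$r_squared, tolerance = 1e-12)
  expect_equal(back$n_pairs, 4)
})
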