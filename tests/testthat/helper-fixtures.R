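# Shared fixtures and independent oracles.
#
# `oracle_logistic()` deliberately re-derives the model curve from the
# written formula (no calls into package internals) so tests that compare
# fits or predictions against it are genuinely dual-route.

oracle_logistic <- function(x, y_max, d50, dx) {
  y_max / (1 + exp((x - d50) / dx))
}

# Brute-force SSE minimum over a (d50, dx) grid for one visit set.
oracle_grid_sse <- function(x, y, d50_grid, dx_grid, y_max = 48) {
  best <- Inf
  for (dd in dx_grid) {
    preds <- outer(d50_grid, x, function(d50, xx) y_max / (1 + exp((xx - d50) / dd)))
    sse <- rowSums(sweep(preds, 2, y)^2)
    best <- min(best, min(sse))
  }
  best
}

# A clean fast-progressor trajectory sampled across its midpoint.
fast_trajectory <- function(d50 = 30, dx = 8, visits = seq(6, 54, by = 6),
                            noise_sd = 0, integerize = FALSE, seed = NULL,
                            id = "FIX") {
  simulate_trajectory(logistic_params(d50 = d50, dx = dx), visits,
                      noise_sd = noise_sd, integerize = integerize,
                      seed = seed, patient_id = id)
}

# Paper-like slow progressor: midpoint far beyond the visit window.
slow_trajectory <- function(d50 = 150, dx = 40, visits = c(8, 15, 22, 30, 38),
                            noise_sd = 2, seed = 7, id = "SLOW") {
  simulate_trajectory(logistic_params(d50 = d50, dx = dx), visits,
                      noise_sd = noise_sd, integerize = TRUE,
                      seed = seed, patient_id = id)
}

quiet_cfg <- function(seed = 1, ...) fit_config(seed = seed, ...)
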