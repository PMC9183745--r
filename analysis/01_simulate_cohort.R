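#!/usr/bin/env Rscript

# Stage 1: simulate a register-like ALS cohort with known ground truth.
#
# The generator emulates the kind of population register cohort the D50
# model was developed on: ~20 patients with sparse irregular follow-up
# (3-11 visits), integer ALSFRS-R totals with measurement noise, a 35%
# slow-progressor share, and an occasional transient score gain.

suppressPackageStartupMessages(library(d50fit))

dir.create("results", showWarnings = FALSE)
cfg <- sim_config(seed = 2022)
sim <- simulate_cohort(cfg)

write_cohort(sim$cohort, "results/cohort.csv")
write.csv(sim$truth, "results/ground_truth.csv", row.names = FALSE)

print(sim$cohort)
nv <- vapply(sim$cohort, n_visits, integer(1))
firsts <- vapply(sim$cohort, function(tr) tr$scores[1], numeric(1))
lasts <- vapply(sim$cohort, function(tr) tr$scores[n_visits(tr)], numeric(1))
message(sprintf("visits/patient: mean %.1f (sd %.1f), range %d-%d",
                mean(nv), sd(nv), min(nv), max(nv)))
message(sprintf("first score %.1f (sd %.1f); last score %.1f (sd %.1f)",
                mean(firsts), sd(firsts), mean(lasts), sd(lasts)))
message(sprintf("true slow progressors: %d of %d",
                sum(sim$truth$class == "slow"), nrow(sim$truth)))
message("wrote results/cohort.csv and results/ground_truth.csv")
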