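#!/usr/bin/env Rscript

# Stage 4: model adequacy and parameter relationships.
#
# (a) observed-vs-predicted agreement (R^2, absolute-agreement ICC,
#     Cronbach's alpha) for a representative converged patient and pooled
#     over all converged fits;
# (b) OLS relationships between the fitted midpoint slope and D50, and
#     between conventionally seeded and optimised D50.

suppressPackageStartupMessages(library(d50fit))

report <- jsonlite::read_json("results/fits_converted.json")
conv <- Filter(function(f) f$status == "converged", report)
stopifnot(length(conv) >= 3)

# representative patient: the converged fit with the most visits
nv <- vapply(conv, function(f) length(f$observed), integer(1))
rep_fit <- conv[[which.max(nv)]]
a_rep <- agreement(unlist(rep_fit$observed), unlist(rep_fit$predicted))
message(sprintf("representative patient %s:", rep_fit$patient_id))
print(a_rep)
write_report_json(a_rep, "results/agreement_representative.json")

obs_all <- unlist(lapply(conv, function(f) unlist(f$observed)))
pred_all <- unlist(lapply(conv, function(f) unlist(f$predicted)))
a_all <- agreement(obs_all, pred_all)
message("pooled over converged patients:")
print(a_all)
write_report_json(a_all, "results/agreement_pooled.json")

tab <- read.csv("results/fits_converted.csv")
conv_tab <- tab[tab$status == "converged", ]
slopes <- 48 / (4 * conv_tab$dx)   # midpoint decline rate of each fitted curve
r1 <- relate_parameters(conv_tab$d50, slopes)
message("fitted midpoint slope vs D50:")
print(r1)
write_report_json(r1, "results/relation_slope_d50.json")

r2 <- relate_parameters(conv_tab$d50, conv_tab$init_d50)
message("conventional (seed) vs optimised D50:")
print(r2)
write_report_json(r2, "results/relation_conventional_d50.json")
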