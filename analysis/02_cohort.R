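#!/usr/bin/env Rscript
# Step 2 — build and characterize the TAF cohort.
#
# Screens adult ART users, applies the exclusion rules (single
# dispensation, >12-month refill gap, transfer out), indexes patients
# at their first TAF dispensation, labels regimen subtype (MTR/STR)
# and treatment experience (naive/switcher), and profiles baseline
# comorbidity with the modified Charlson score over the lookback year.

library(artclaims)
library(dplyr)

tabs <- read_tables("results/data")
built <- build_cohort(tabs, cohort_spec())
coh <- built$cohort

readr::write_csv(coh, "results/cohort.csv", na = "")
readr::write_csv(built$attrition, "results/attrition.csv")
readr::write_csv(built$excluded, "results/exclusions.csv")

cat("Attrition:\n")
print(as.data.frame(built$attrition), row.names = FALSE)
cat("\nExclusions by reason:\n")
print(table(built$excluded$reason))

cat(sprintf("\nTAF cohort: %d patients, mean age %.1f, %.1f%% male\n",
            nrow(coh), mean(coh$age_at_index),
            100 * mean(coh$sex == "M")))
cat(sprintf("Subtype: %.0f%% MTR / %.0f%% STR;  experience: %.0f%% naive / %.0f%% switcher\n",
            100 * mean(coh$taf_subtype == "MTR"),
            100 * mean(coh$taf_subtype == "STR"),
            100 * mean(coh$experience == "naive"),
            100 * mean(coh$experience == "switcher")))

conds <- names(default_comorbidity_map())
prev <- sort(100 * colMeans(as.matrix(coh[conds])), decreasing = TRUE)
cat("\nBaseline comorbidity prevalence (%):\n")
print(round(prev, 1))
cat(sprintf("\nCCI: mean %.2f;  %.1f%% score 0, %.1f%% score 1, %.1f%% score >=2\n",
            mean(coh$cci), 100 * mean(coh$cci == 0),
            100 * mean(coh$cci == 1), 100 * mean(coh$cci >= 2)))
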