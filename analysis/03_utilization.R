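#!/usr/bin/env Rscript
# Step 3 — adherence, persistence, switch and discontinuation.
#
# Computes TAF-scope PDC over the 365-day first-year window with
# carry-forward coverage, applies the >95% and >85% adherence
# thresholds, and classifies each patient from dispensing in the last
# quarter of follow-up year 1 (days 274-364 after index).

library(artclaims)

tabs <- read_tables("results/data")
coh <- readr::read_csv("results/cohort.csv", show_col_types = FALSE)

util <- compute_utilization(tabs, coh, cohort_spec())
summ <- summarize_utilization(util, coh)

readr::write_csv(util, "results/utilization.csv", na = "")
readr::write_csv(summ, "results/utilization_summary.csv")

cat("Drug utilization, overall and by subgroup (%):\n")
print(as.data.frame(summ[, c("group", "n", "pct_adherent_95",
                             "pct_adherent_85", "pct_persistent",
                             "pct_switched", "pct_discontinued")]),
      row.names = FALSE, digits = 3)
ov <- summ[summ$group == "overall", ]
cat(sprintf("\nPersistence to any ART: %.1f%% (vs %.1f%% to the TAF regimen)\n",
            ov$pct_persistent_any_art, ov$pct_persistent))
cat(sprintf("Mean PDC %.1f%%; adherence strata: %.1f%% <80, %.1f%% 81-95, %.1f%% >95\n",
            mean(util$pdc),
            100 * mean(util$adherence_stratum == "<80"),
            100 * mean(util$adherence_stratum == "81-95"),
            100 * mean(util$adherence_stratum == ">95")))

# agreement with generator ground truth, as a self-check
gt <- tabs$ground_truth
m <- merge(util, gt, by = "patient_id")
cat(sprintf("\nStatus agreement with ground truth: %.2f%%\n",
            100 * mean(m$status.x == m$status.y)))
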