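#!/usr/bin/env Rscript
# Step 4 — annualized resource use and direct costs.
#
# Tallies the five cost items per patient for the first follow-up year
# and for all available follow-up, removes outliers (total cost above
# mean + 3 SD, single pass), and stratifies mean annual costs by
# persistence, adherence stratum and inclusion year. An ART-vs-TAF
# comparison over all follow-up uses the non-TAF ART patients of the
# same generated population. Bar charts go to results/figures/.

library(artclaims)
library(dplyr)

`%||%` <- function(a, b) if (length(a)) a else b

tabs <- read_tables("results/data")
coh <- readr::read_csv("results/cohort.csv", show_col_types = FALSE)
util <- readr::read_csv("results/utilization.csv", show_col_types = FALSE)

strata_tables <- list()
for (win in c("first_year", "all_followup")) {
  tal <- tally_resources(tabs, coh, cohort_spec(), window = win)
  excl <- exclude_outliers(tal)
  keep <- excl$retained
  readr::write_csv(keep, sprintf("results/costs_%s.csv", win))
  cat(sprintf("\n== %s window: %d patients, %d outliers above EUR %.0f ==\n",
              win, nrow(tal), length(excl$excluded_ids), excl$threshold))
  cat(sprintf("Mean annual total cost EUR %.0f (ART drugs %.0f, other drugs %.0f, HIV hosp %.0f, other hosp %.0f, outpatient %.0f)\n",
              mean(keep$cost_total), mean(keep$cost_hiv_drugs),
              mean(keep$cost_other_drugs), mean(keep$cost_hiv_hosp),
              mean(keep$cost_other_hosp), mean(keep$cost_outpatient)))

  labs <- list(
    persistence = transmute(util, patient_id,
                            stratum = ifelse(status == "persistent",
                                             "persistent",
                                             "non_persistent")),
    adherence = transmute(util, patient_id,
                          stratum = as.character(adherence_stratum)),
    year = transmute(coh, patient_id,
                     stratum = as.character(inclusion_year)))
  for (s in names(labs)) {
    st <- stratify_costs(keep, labs[[s]])
    strata_tables[[paste(win, s, sep = "_")]] <-
      mutate(st$summary, analysis = paste(win, s, sep = "_"), .before = 1)
    if (s == "persistence") {
      tot <- st$comparisons[st$comparisons$item == "cost_total", ]
      hiv <- st$comparisons[st$comparisons$item == "cost_hiv_hosp", ]
      cat(sprintf("Persistent vs non-persistent total: EUR %.0f vs %.0f (p = %.3g); HIV-hosp item: %.0f vs %.0f (p = %.3g)\n",
                  tot$mean_a[tot$group_a == "persistent"] %||% tot$mean_b,
                  tot$mean_b[tot$group_a == "persistent"] %||% tot$mean_a,
                  tot$p_value,
                  hiv$mean_a[hiv$group_a == "persistent"] %||% hiv$mean_b,
                  hiv$mean_b[hiv$group_a == "persistent"] %||% hiv$mean_a,
                  hiv$p_value))
    }
  }
}
readr::write_csv(bind_rows(strata_tables), "results/costs_by_stratum.csv")

# ART (non-TAF) vs TAF over all follow-up, among adherent (>95%) users:
# the non-TAF patients of the same population serve as comparator, with
# index at their first ART dispensation
gt <- tabs$ground_truth
nontaf <- gt[!gt$is_taf, ]
demo <- tabs$demographics
pseudo <- tibble::tibble(patient_id = nontaf$patient_id,
                         index_date = nontaf$index_date) |>
  inner_join(demo[, c("patient_id", "enrollment_end", "death_date",
                      "transfer_out")], by = "patient_id") |>
  filter(!transfer_out) |>
  mutate(followup_end = pmin(enrollment_end,
                             coalesce(death_date, enrollment_end))) |>
  select(patient_id, index_date, followup_end)
tal_nontaf <- exclude_outliers(
  tally_resources(tabs, pseudo, cohort_spec(), "all_followup"))$retained
tal_taf <- readr::read_csv("results/costs_all_followup.csv",
                           show_col_types = FALSE)
adh_taf <- filter(util, adherent_95)$patient_id
util_nontaf <- compute_utilization(
  tabs, mutate(pseudo, followup_end = followup_end),
  cohort_spec(), pdc_scope = "any_art")
cmp <- compare_groups(
  filter(tal_nontaf, patient_id %in%
           filter(util_nontaf, adherent_95)$patient_id)$cost_total,
  filter(tal_taf, patient_id %in% adh_taf)$cost_total)
cat(sprintf("\nAdherent (>95%%) non-TAF ART vs TAF, all follow-up: difference EUR %.0f (p = %.3g)\n",
            cmp$difference, cmp$p_value))

# figures
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
  plot_df <- bind_rows(strata_tables) |>
    filter(item != "cost_total",
           analysis %in% c("first_year_persistence",
                           "first_year_adherence", "first_year_year"))
  p <- ggplot(plot_df, aes(stratum, mean, fill = item)) +
    geom_col() +
    facet_wrap(~analysis, scales = "free_x") +
    labs(x = NULL, y = "Mean annual cost (EUR)",
         title = "Mean annual healthcare costs by stratum, first year") +
    theme_minimal()
  ggsave("results/figures/costs_by_stratum.png", p,
         width = 10, height = 4.5, dpi = 150)
  cat("Figure written to results/figures/costs_by_stratum.png\n")
}
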