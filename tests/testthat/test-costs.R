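spec <- cohort_spec()

# a minimal one-patient cohort row as tally_resources needs it
mini_cohort <- function(id = "A", index = "2017-01-01",
                        fu_end = "2020-12-31") {
  tibble::tibble(patient_id = id, index_date = as.Date(index),
                 followup_end = as.Date(fu_end))
}

test_that("resource tallies classify and annualize events", {
  idx <- as.Date("2017-01-01")
  tabs <- fixture_tables(
    demo_row("A"),
    pharmacy = dplyr::bind_rows(
      disp_rows("A", "J05AR20", monthly(idx, 12), cost = 600),
      disp_rows("A", "C10AA05", idx + 40, cost = 12.34)),
    hospital = dplyr::bind_rows(
      hosp_rows("A", idx + 100, "042", drg = "489", tariff = 5000),
      hosp_rows("A", idx + 200, "540", drg = "127", tariff = 2000)),
    outpatient = outp_rows("A", idx + seq(10, 700, length.out = 10)))

  fy <- tally_resources(tabs, mini_cohort(), spec, window = "first_year")
  expect_equal(fy$n_hiv_drug_disp, 12)
  expect_equal(fy$n_other_drug_disp, 1)
  expect_equal(fy$n_hiv_hosp, 1)
  expect_equal(fy$n_other_hosp, 1)
  expect_equal(fy$cost_hiv_drugs, 7200)
  expect_equal(fy$cost_other_drugs, 12.34)
  expect_equal(fy$cost_hiv_hosp, 5000)
  expect_equal(fy$cost_other_hosp, 2000)
  expect_equal(fy$cost_total,
               fy$cost_hiv_drugs + fy$cost_other_drugs + fy$cost_hiv_hosp +
                 fy$cost_other_hosp + fy$cost_outpatient)

  # 10 outpatient services over a 730-day follow-up ~ 5 per year
  tabs2 <- fixture_tables(
    demo_row("A"), pharmacy = disp_rows("A", "J05AR20", monthly(idx, 2)),
    outpatient = outp_rows("A", idx + seq(10, 700, length.out = 10)))
  af <- tally_resources(tabs2, mini_cohort(fu_end = idx + 730), spec,
                        window = "all_followup")
  expect_equal(af$person_years, 730 / 365.25)
  expect_equal(af$n_outpatient, 10 / (730 / 365.25))
  expect_equal(af$n_outpatient, 5, tolerance = 0.01)
})

test_that("unknown DRGs are tallied as other-cause admissions with a note", {
  idx <- as.Date("2017-01-01")
  tabs <- fixture_tables(
    demo_row("A"), pharmacy = disp_rows("A", "J05AR20", monthly(idx, 12)),
    hospital = hosp_rows("A", idx + 50, "540", drg = "999", tariff = 100))
  expect_message(
    fy <- tally_resources(tabs, mini_cohort(), spec, "first_year"),
    "outside the configured dictionary")
  expect_equal(fy$n_other_hosp, 1)
  expect_equal(fy$cost_other_hosp, 100)
})

test_that("patients dead before the window end are excluded from that window", {
  idx <- as.Date("2017-01-01")
  demo <- dplyr::bind_rows(
    demo_row("dead", death = as.character(idx + 200),
             enroll_end = as.character(idx + 200)),
    demo_row("alive"))
  tabs <- fixture_tables(
    demo, pharmacy = dplyr::bind_rows(
      disp_rows("dead", "J05AR20", monthly(idx, 6)),
      disp_rows("alive", "J05AR20", monthly(idx, 13))))
  coh <- dplyr::bind_rows(mini_cohort("dead", fu_end = idx + 200),
                          mini_cohort("alive"))
  fy <- tally_resources(tabs, coh, spec, "first_year")
  expect_identical(fy$patient_id, "alive")
})

test_that("item costs sum to totals to the cent on generated cohorts", {
  cfg <- claims_config(n_patients = 300, seed = 77)
  tabs <- generate_cohort_tables(cfg)
  built <- build_cohort(tabs)
  for (win in c("first_year", "all_followup")) {
    tal <- tally_resources(tabs, built$cohort, spec, win)
    items <- as.matrix(tal[paste0("cost_", c("hiv_drugs", "other_drugs",
                                             "hiv_hosp", "other_hosp",
                                             "outpatient"))])
    expect_equal(rowSums(items), tal$cost_total, tolerance = 1e-9)
  }
})

test_that("outlier rule: mean + 3 SD, strict, single pass", {
  bd <- tibble::tibble(patient_id = as.character(1:4),
                       cost_total = c(1, 1, 1, 100))
  res <- exclude_outliers(bd)
  expect_equal(res$threshold, mean(c(1, 1, 1, 100)) +
                 3 * sd(c(1, 1, 1, 100)))
  expect_equal(res$threshold, 174.25)
  expect_length(res$excluded_ids, 0)

  flat <- tibble::tibble(patient_id = as.character(1:10),
                         cost_total = rep(5, 10))
  expect_length(exclude_outliers(flat)$excluded_ids, 0)

  # one extreme value in a near-constant cohort is the only exclusion
  set.seed(9)
  big <- tibble::tibble(patient_id = sprintf("p%04d", 1:1000),
                        cost_total = rnorm(1000, 1000, 20))
  big$cost_total[417] <- 10 * mean(big$cost_total)
  res2 <- exclude_outliers(big)
  expect_identical(res2$excluded_ids, "p0417")

  expect_warning(res1 <- exclude_outliers(bd[1, ]), "fewer than 2")
  expect_length(res1$excluded_ids, 0)
})

test_that("stratified means recombine to the overall mean", {
  cfg <- claims_config(n_patients = 400, seed = 13)
  tabs <- generate_cohort_tables(cfg)
  built <- build_cohort(tabs)
  util <- compute_utilization(tabs, built$cohort)
  tal <- tally_resources(tabs, built$cohort, spec, "first_year")
  keep <- exclude_outliers(tal)$retained
  labels <- dplyr::transmute(
    util, patient_id,
    stratum = ifelse(status == "persistent", "persistent",
                     "non_persistent"))
  strat <- stratify_costs(keep, labels)
  tot <- strat$summary[strat$summary$item == "cost_total", ]
  expect_equal(sum(tot$n * tot$mean) / sum(tot$n), mean(keep$cost_total),
               tolerance = 1e-9)
  expect_equal(sum(tot$n), nrow(keep))
  # two strata -> Welch comparisons per cost item
  expect_s3_class(strat$comparisons, "tbl_df")
  expect_true("cost_total" %in% strat$comparisons$item)
})

test_that("identical cost distributions in both strata give zero difference", {
  vals <- c(100, 200, 300, 400, 500)
  bd <- tibble::tibble(patient_id = as.character(1:10),
                       cost_total = rep(vals, 2),
                       cost_hiv_drugs = 0, cost_other_drugs = 0,
                       cost_hiv_hosp = 0, cost_other_hosp = 0,
                       cost_outpatient = rep(vals, 2))
  labels <- tibble::tibble(patient_id = as.character(1:10),
                           stratum = rep(c("a", "b"), each = 5))
  strat <- stratify_costs(bd, labels)
  tot <- strat$comparisons[strat$comparisons$item == "cost_total", ]
  expect_equal(tot$difference, 0)
  expect_equal(tot$p_value, 1)
  # a single stratum reduces to the unstratified summary, no comparisons
  one <- stratify_costs(bd, dplyr::mutate(labels, stratum = "all"))
  expect_null(one$comparisons)
  expect_equal(one$summary$mean[one$summary$item == "cost_total"],
               mean(bd$cost_total))
})

test_that("persistence-dependent admission rates surface as a cost gap", {
  hits <- vapply(1:5, function(s) {
    cfg <- claims_config(n_patients = 2000, seed = 1000 + s)
    tabs <- generate_cohort_tables(cfg)
    built <- build_cohort(tabs)
    util <- compute_utilization(tabs, built$cohort)
    tal <- tally_resources(tabs, built$cohort, spec, "first_year")
    keep <- exclude_outliers(tal)$retained
    df <- dplyr::inner_join(keep, util[, c("patient_id", "status")],
                            by = "patient_id")
    mean(df$cost_hiv_hosp[df$status != "persistent"]) >
      mean(df$cost_hiv_hosp[df$status == "persistent"])
  }, logical(1))
  expect_true(all(hits))
})
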