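test_that("coverage building: simple, carry-forward, truncation, pre-index", {
  idx <- as.Date("2017-01-01")
  one <- build_coverage(disp_rows("A", "J05AR20", idx), idx, 365)
  expect_equal(as.data.frame(one$intervals),
               data.frame(start = 0L, end = 30L))
  expect_equal(one$covered_days, 30)

  # early refill at day 20 stockpiles: coverage runs [0, 60)
  cf <- build_coverage(disp_rows("A", "J05AR20", idx + c(0, 20)), idx, 365)
  expect_equal(as.data.frame(cf$intervals),
               data.frame(start = 0L, end = 60L))

  # dispensation at day 360 truncates at the window edge
  tr <- build_coverage(disp_rows("A", "J05AR20", idx + 360), idx, 365)
  expect_equal(as.data.frame(tr$intervals),
               data.frame(start = 360L, end = 365L))
  expect_equal(tr$covered_days, 5)

  expect_warning(
    pre <- build_coverage(disp_rows("A", "J05AR20", idx + c(-10, 0)),
                          idx, 365),
    "before the index")
  expect_equal(pre$covered_days, 30)
  expect_error(build_coverage(disp_rows("A", "J05AR20", idx), idx, 0),
               "positive")
})

test_that("PDC is the covered-day ratio, capped at 100", {
  idx <- as.Date("2017-01-01")
  ten <- build_coverage(disp_rows("A", "J05AR20", monthly(idx, 10)),
                        idx, 365)
  expect_equal(ten$covered_days, 300)
  expect_equal(compute_pdc(ten), 100 * 300 / 365)
  expect_equal(round(compute_pdc(ten), 2), 82.19)

  full <- build_coverage(disp_rows("A", "J05AR20", monthly(idx, 13)),
                         idx, 365)
  expect_equal(compute_pdc(full), 100)
})

test_that("interval-union PDC equals the boolean-calendar oracle on random streams", {
  set.seed(404)
  for (r in 1:200) {
    k <- sample(1:20, 1)
    day <- sort(sample(0:420, k, replace = TRUE))
    supply <- sample(c(15L, 30L, 60L), k, replace = TRUE)
    idx <- as.Date("2017-01-01")
    disp <- disp_rows("A", "J05AR20", idx + day, packs = 1L, units = supply)
    pdc <- compute_pdc(build_coverage(disp, idx, 365))
    expect_equal(pdc, oracle_pdc(day, supply, 365), tolerance = 1e-12)
  }
})

test_that("adding a dispensation never decreases PDC", {
  set.seed(405)
  idx <- as.Date("2017-01-01")
  for (r in 1:50) {
    k <- sample(2:15, 1)
    day <- sort(sample(0:400, k))
    disp <- disp_rows("A", "J05AR20", idx + day)
    base <- compute_pdc(build_coverage(disp, idx, 365))
    more <- dplyr::bind_rows(disp, disp_rows("A", "J05AR20",
                                             idx + sample(0:400, 1)))
    expect_gte(compute_pdc(build_coverage(more, idx, 365)), base)
    fewer <- disp[-sample(k, 1), ]
    expect_lte(compute_pdc(build_coverage(fewer, idx, 365)), base)
  }
})

test_that("adherence thresholds are strict and strata partition [0, 100]", {
  res <- classify_adherence(c(96, 90, 95, 80, 80.5, 0, 100))
  expect_equal(res$adherent_95, c(TRUE, FALSE, FALSE, FALSE, FALSE,
                                  FALSE, TRUE))
  expect_equal(res$adherent_85, c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                  FALSE, TRUE))
  expect_equal(as.character(res$adherence_stratum),
               c(">95", "81-95", "81-95", "<80", "81-95", "<80", ">95"))
  expect_error(classify_adherence(101), "\\[0, 100\\]")
  expect_error(classify_adherence(-1), "\\[0, 100\\]")
})

test_that("status classification: persistent, discontinued, switched, censored", {
  spec <- cohort_spec()
  idx <- as.Date("2017-01-01")
  fu <- as.Date("2018-06-30")

  persist <- disp_rows("A", "J05AR20", monthly(idx, 13))
  expect_equal(classify_status(persist, idx, fu, spec)$status, "persistent")

  stopped <- disp_rows("A", "J05AR20", monthly(idx, 7))  # last at day 180
  st <- classify_status(stopped, idx, fu, spec)
  expect_equal(st$status, "discontinued")
  expect_false(st$persistent_any_art)

  switched <- dplyr::bind_rows(
    disp_rows("A", "J05AR20", monthly(idx, 7)),
    disp_rows("A", "J05AR13", monthly(idx + 230, 5)))
  sw <- classify_status(switched, idx, fu, spec)
  expect_equal(sw$status, "switched")
  expect_true(sw$persistent_any_art)
  expect_false(sw$persistent_taf)
  expect_equal(sw$switch_date, idx + 230)

  # death at day 200: evaluation window is the last quarter of the
  # truncated follow-up, and the result is flagged censored
  cens <- classify_status(disp_rows("A", "J05AR20", monthly(idx, 7)),
                          idx, idx + 200, spec)
  expect_true(cens$censored)
  expect_equal(cens$status, "persistent")  # refills cover days [150, 200)
})

test_that("the coverage-in-window persistence rule counts supply, not dates", {
  spec <- cohort_spec()
  idx <- as.Date("2017-01-01")
  fu <- as.Date("2018-12-31")
  # last dispensation at day 260 with 30-day supply: coverage reaches
  # day 290, inside the last quarter, but no dispensation date is
  disp <- disp_rows("A", "J05AR20", monthly(idx, 9) + 20)  # days 20..260
  by_date <- classify_status(disp, idx, fu, spec,
                             persistence_rule = "date_in_window")
  by_cov <- classify_status(disp, idx, fu, spec,
                            persistence_rule = "coverage_in_window")
  expect_equal(by_date$status, "discontinued")
  expect_equal(by_cov$status, "persistent")
})

test_that("statuses partition generated cohorts and threshold sets nest", {
  cfg <- claims_config(n_patients = 600, seed = 31)
  tabs <- generate_cohort_tables(cfg)
  built <- build_cohort(tabs)
  util <- compute_utilization(tabs, built$cohort)
  expect_equal(sum(util$status == "persistent") +
                 sum(util$status == "switched") +
                 sum(util$status == "discontinued"), nrow(util))
  expect_true(all(util$adherent_85[util$adherent_95]))
  expect_true(all(util$persistent_any_art[util$persistent_taf]))
  # vectorized classification agrees with the per-patient operation
  for (pid in util$patient_id[seq(1, nrow(util), length.out = 12)]) {
    coh <- built$cohort[built$cohort$patient_id == pid, ]
    ph <- tabs$pharmacy[tabs$pharmacy$patient_id == pid, ]
    single <- classify_status(ph, coh$index_date, coh$followup_end)
    expect_equal(util$status[util$patient_id == pid], single$status)
  }
})

test_that("utilization summaries report proportions that add up", {
  cfg <- claims_config(n_patients = 400, seed = 57)
  tabs <- generate_cohort_tables(cfg)
  built <- build_cohort(tabs)
  util <- compute_utilization(tabs, built$cohort)
  s <- summarize_utilization(util, built$cohort)
  expect_equal(s$pct_persistent + s$pct_switched + s$pct_discontinued,
               rep(100, nrow(s)))
  expect_true(all(s$pct_adherent_95 <= s$pct_adherent_85))
  expect_setequal(s$group, c("overall", "MTR", "STR", "naive", "switcher"))
  expect_identical(summarize_utilization(util[0, ]), tibble::tibble())
})
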