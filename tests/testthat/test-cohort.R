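spec <- cohort_spec()

test_that("screening enforces adulthood at first ART dispensation", {
  # 17 years old at first ART -> excluded; an 18-year-old twin passes
  demo <- dplyr::bind_rows(
    demo_row("young", birth = "2000-06-01"),
    demo_row("adult", birth = "1998-06-01"))
  ph <- dplyr::bind_rows(
    disp_rows("young", "J05AR20", monthly("2018-03-01", 3)),
    disp_rows("adult", "J05AR20", monthly("2018-03-01", 3)))
  tabs <- fixture_tables(demo, ph)
  expect_identical(screen_art_patients(tabs, spec), "adult")
})

test_that("patients without ART-class dispensations are not screened", {
  tabs <- fixture_tables(
    demo_row("A"),
    disp_rows("A", "C10AA05", monthly("2017-01-01", 12)))
  expect_length(screen_art_patients(tabs, spec), 0)
})

test_that("missing birth dates are skipped with a warning", {
  demo <- demo_row("A")
  demo$birth_date <- as.Date(NA)
  tabs <- fixture_tables(demo, disp_rows("A", "J05AR20",
                                         monthly("2017-01-01", 3)))
  expect_warning(ids <- screen_art_patients(tabs, spec), "birth date")
  expect_length(ids, 0)
})

test_that("exclusion rules: single dispensation, long gap, transfer", {
  demo <- dplyr::bind_rows(
    demo_row("single"), demo_row("gap"), demo_row("ok"),
    demo_row("moved", transfer = TRUE, enroll_end = "2018-06-01"))
  ph <- dplyr::bind_rows(
    disp_rows("single", "J05AR20", "2017-05-01"),
    disp_rows("gap", "J05AR20", as.Date(c("2016-01-01", "2017-02-05"))),
    disp_rows("ok", "J05AR20", monthly("2016-01-01", 24)),
    disp_rows("moved", "J05AR20", monthly("2017-01-01", 12)))
  tabs <- fixture_tables(demo, ph)
  excl <- apply_exclusions(c("single", "gap", "ok", "moved"), tabs, spec)
  expect_identical(excl$keep, "ok")
  reasons <- setNames(excl$excluded$reason, excl$excluded$patient_id)
  expect_equal(reasons[["single"]], "single_art_dispensation")
  expect_equal(reasons[["gap"]], "art_gap_over_limit")
  expect_equal(reasons[["moved"]], "transfer_out")
})

test_that("a 365-day refill gap is tolerated, 366 is not", {
  demo <- dplyr::bind_rows(demo_row("edge"), demo_row("over"))
  ph <- dplyr::bind_rows(
    disp_rows("edge", "J05AR20",
              as.Date("2016-01-01") + c(0, 365, 395)),
    disp_rows("over", "J05AR20",
              as.Date("2016-01-01") + c(0, 366, 396)))
  tabs <- fixture_tables(demo, ph)
  excl <- apply_exclusions(c("edge", "over"), tabs, spec)
  expect_identical(excl$keep, "edge")
})

test_that("index dating and regimen / experience labels follow the rules", {
  demo <- dplyr::bind_rows(demo_row("str_sw"), demo_row("mtr_nv"))
  ph <- dplyr::bind_rows(
    # prior non-TAF ART 100 days before the first TAF -> switcher; the
    # first TAF dispensation is a bictegravir combination -> STR
    disp_rows("str_sw", "J05AR13", monthly("2016-10-23", 4)),
    disp_rows("str_sw", "J05AR20", monthly("2017-03-01", 14)),
    # no dispensation of any kind before index -> naive; TAF alone -> MTR
    disp_rows("mtr_nv", "J05AF13", monthly("2017-06-01", 14)))
  tabs <- fixture_tables(demo, ph)
  coh <- index_and_label(c("str_sw", "mtr_nv"), tabs, spec)
  coh <- coh[order(coh$patient_id), ]
  expect_equal(coh$patient_id, c("mtr_nv", "str_sw"))
  expect_equal(coh$index_date,
               as.Date(c("2017-06-01", "2017-03-01")))
  expect_equal(coh$taf_subtype, c("MTR", "STR"))
  expect_equal(coh$experience, c("naive", "switcher"))
})

test_that("the lookback is half-open: ART on the index date keeps naive status", {
  demo <- demo_row("A")
  ph <- dplyr::bind_rows(
    disp_rows("A", "J05AR13", "2017-03-01"),   # same day as first TAF
    disp_rows("A", "J05AR20", monthly("2017-03-01", 14)))
  tabs <- fixture_tables(demo, ph)
  coh <- index_and_label("A", tabs, spec)
  expect_equal(coh$experience, "naive")

  # one day earlier voids it
  ph2 <- dplyr::bind_rows(
    disp_rows("A", "J05AR13", "2017-02-28"),
    disp_rows("A", "J05AR20", monthly("2017-03-01", 14)))
  coh2 <- index_and_label("A", fixture_tables(demo, ph2), spec)
  expect_equal(coh2$experience, "switcher")
})

test_that("baseline characterization flags lookback codes and scores the modified CCI", {
  demo <- demo_row("A")
  taf <- disp_rows("A", "J05AR20", monthly("2017-03-01", 14))

  # diabetes drugs only -> single weight-1 condition
  tabs <- fixture_tables(demo, dplyr::bind_rows(
    taf, disp_rows("A", "A10BA02", "2016-09-01")))
  coh <- characterize_baseline(index_and_label("A", tabs, spec), tabs, spec)
  expect_true(coh$diabetes)
  expect_equal(coh$cci, 1L)

  # no baseline events -> all flags false, CCI 0
  tabs0 <- fixture_tables(demo, taf)
  coh0 <- characterize_baseline(index_and_label("A", tabs0, spec),
                                tabs0, spec)
  expect_equal(coh0$cci, 0L)
  expect_false(any(unlist(coh0[names(spec$comorbidity_map)])))

  # metastatic tumor (weight 6) + diabetes (1) -> 7
  tabs7 <- fixture_tables(
    demo,
    dplyr::bind_rows(taf, disp_rows("A", "A10BA02", "2016-09-01")),
    hosp_rows("A", "2016-11-15", "1970"))
  coh7 <- characterize_baseline(index_and_label("A", tabs7, spec),
                                tabs7, spec)
  expect_true(coh7$metastatic_cancer)
  expect_equal(coh7$cci, 7L)
})

test_that("characterization ignores events on or after the index date", {
  demo <- demo_row("A")
  taf <- disp_rows("A", "J05AR20", monthly("2017-03-01", 14))
  tabs <- fixture_tables(
    demo,
    dplyr::bind_rows(taf,
                     disp_rows("A", "A10BA02", "2017-03-01"),   # on index
                     disp_rows("A", "C10AA05", "2017-05-01")),  # after
    hosp_rows("A", "2017-06-01", "1970"))
  coh <- characterize_baseline(index_and_label("A", tabs, spec), tabs, spec)
  expect_false(coh$diabetes)
  expect_false(coh$dyslipidemia)
  expect_false(coh$metastatic_cancer)
  expect_equal(coh$cci, 0L)
})

test_that("cohort labels agree with generator ground truth", {
  cfg <- claims_config(n_patients = 2000, seed = 23)
  tabs <- generate_cohort_tables(cfg)
  built <- build_cohort(tabs)
  m <- dplyr::inner_join(built$cohort, tabs$ground_truth,
                         by = "patient_id", suffix = c("", ".gt"))
  expect_gt(nrow(m), 800)
  expect_gte(mean(m$taf_subtype == m$taf_subtype.gt), 0.99)
  expect_gte(mean(m$experience == m$experience.gt), 0.99)
  # subtype and experience each partition the TAF cohort
  expect_true(all(built$cohort$taf_subtype %in% c("MTR", "STR")))
  expect_true(all(built$cohort$experience %in% c("naive", "switcher")))
})
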