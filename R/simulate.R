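# Synthetic administrative-claims generator.
#
# Emits the four linked tables the analysis consumes (demographics,
# pharmacy, hospital, outpatient) plus a ground-truth table, with the
# statistical structure the pipeline assumes: per-patient target PDC
# realized through a geometric refill-delay process, persistence /
# switch / discontinuation behavior expressed in the dispensation
# streams, comorbidity code trails in the characterization period, and
# persistence-dependent HIV hospitalization rates.

# Refill streams: each dispensation supplies `supply` days; the next
# refill is delayed by a geometric number of extra days with mean
# supply * (1 - p) / p, so expected long-run coverage equals the target
# PDC p. Returns a tibble with patient row index and day offset.
make_refill_days <- function(start_day, stop_day, target_pdc, supply) {
  n <- length(start_day)
  empty <- tibble::tibble(i = integer(), day = integer())
  if (n == 0) return(empty)
  span <- pmax(stop_day - start_day, 0L)
  if (max(span) == 0) return(empty)
  p <- pmin(pmax(target_pdc, 0.05), 1)
  prob <- 1 / (1 + supply * (1 - p) / p)
  K <- as.integer(ceiling(max(span) / supply)) + 1L
  extra <- matrix(stats::rgeom(n * K, prob = rep(prob, K)), n, K)
  gaps <- supply + extra
  cg <- matrixStats_rowCumsums(gaps)
  days <- cbind(start_day, start_day + cg[, -K, drop = FALSE])
  keep <- days < rep(stop_day, K)
  tibble::tibble(i = rep(seq_len(n), times = K)[keep],
                 day = as.integer(days[keep]))
}

# Row-wise cumulative sums without looping in R per element.
matrixStats_rowCumsums <- function(m) {
  t(apply(m, 1L, cumsum))
}

rgamma_eur <- function(n, par) {
  round(stats::rgamma(n, shape = par[["shape"]], scale = par[["scale"]]), 2)
}

sample_vec <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

empty_tables <- function() {
  list(
    demographics = tibble::tibble(
      patient_id = character(), sex = character(),
      birth_date = as.Date(character()),
      enrollment_start = as.Date(character()),
      enrollment_end = as.Date(character()),
      death_date = as.Date(character()),
      transfer_out = logical()),
    pharmacy = tibble::tibble(
      patient_id = character(), atc_code = character(),
      dispensation_date = as.Date(character()),
      n_packages = integer(), units_per_package = integer(),
      cost_eur = numeric()),
    hospital = tibble::tibble(
      patient_id = character(),
      admission_date = as.Date(character()),
      discharge_date = as.Date(character()),
      icd9_codes = character(), drg_code = character(),
      tariff_eur = numeric()),
    outpatient = tibble::tibble(
      patient_id = character(), service_date = as.Date(character()),
      service_type = character(), tariff_eur = numeric()),
    ground_truth = tibble::tibble(
      patient_id = character(), is_taf = logical(),
      taf_subtype = character(), experience = character(),
      target_pdc = numeric(), status = character(),
      index_date = as.Date(character()))
  )
}

#' Generate linked synthetic claims tables
#'
#' Draws a full cohort under the conditions of a [claims_config()]:
#' demographics, ART dispensation streams (index regimen, pre-index ART
#' for switchers, replacement ART for patients who switch regimen
#' class, companion third agents for multi-tablet regimens), chronic
#' comorbidity medication and baseline comorbidity admissions,
#' follow-up hospitalizations with HIV admissions (DRG 488/489/490)
#' drawn at the rate of the patient's persistence label, and outpatient
#' services. All randomness flows from `config$seed` through per-stage
#' sub-seeds, so results are reproducible.
#'
#' @param config A [claims_config()].
#' @return Named list of tibbles: `demographics`, `pharmacy`,
#'   `hospital`, `outpatient`, `ground_truth`.
#' @export
generate_cohort_tables <- function(config) {
  if (!inherits(config, "claims_config"))
    stop("`config` must be a `claims_config` object", call. = FALSE)
  cfg <- config
  n <- cfg$n_patients
  if (n == 0) return(empty_tables())

  set.seed(cfg$seed)
  ss <- sample.int(2147483646L, 5)

  ## ---- patients --------------------------------------------------------
  set.seed(ss[1])
  patient_id <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < cfg$male_fraction, "M", "F")
  age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  while (any(bad <- age < 18 | age > 95))
    age[bad] <- stats::rnorm(sum(bad), cfg$age_mean, cfg$age_sd)
  is_taf <- stats::runif(n) < cfg$taf_fraction
  taf_subtype <- ifelse(is_taf,
                        ifelse(stats::runif(n) < cfg$str_fraction_given_taf,
                               "STR", "MTR"), NA_character_)
  experience <- ifelse(is_taf,
                       ifelse(stats::runif(n) < cfg$naive_fraction_given_taf,
                              "naive", "switcher"), NA_character_)
  status <- sample(c("persistent", "switched", "discontinued"), n,
                   replace = TRUE,
                   prob = c(cfg$persistence_prob, cfg$switch_prob,
                            1 - cfg$persistence_prob - cfg$switch_prob))
  target_pdc <- sample_pdc_targets(cfg$pdc_target_distribution, n)

  idx_min <- max(cfg$inclusion_start, cfg$study_start + 365L)
  idx_max <- min(cfg$inclusion_end, cfg$study_end - 365L)
  index_date <- idx_min +
    sample.int(as.integer(idx_max - idx_min) + 1L, n, replace = TRUE) - 1L
  birth_date <- index_date - round(age * 365.25)

  transfer <- stats::runif(n) < cfg$transfer_prob
  max_fu <- as.integer(cfg$study_end - index_date)
  death <- !transfer & stats::runif(n) < cfg$death_prob & max_fu > 430L
  death_day <- rep(NA_integer_, n)
  death_day[death] <- 400L +
    floor(stats::runif(sum(death)) * (max_fu[death] - 400L))
  death_date <- index_date + death_day
  enrollment_end <- cfg$study_end + integer(n)
  enrollment_end[transfer] <- index_date[transfer] +
    sample_vec(120:330, sum(transfer))
  enrollment_end[death] <- death_date[death]
  enrollment_start <- rep(cfg$study_start, n)
  followup_days <- as.integer(enrollment_end - index_date)

  demographics <- tibble::tibble(
    patient_id = patient_id, sex = sex, birth_date = birth_date,
    enrollment_start = enrollment_start, enrollment_end = enrollment_end,
    death_date = death_date, transfer_out = transfer)

  ## ---- ART dispensation streams ---------------------------------------
  set.seed(ss[2])
  supply <- cfg$n_packages * cfg$units_per_package
  non_taf_pool <- c("J05AR10", "J05AR13", "J05AE08", "J05AF05")
  companion_pool <- c("J05AG03", "J05AJ03")
  atc_index <- character(n)
  atc_index[is_taf & taf_subtype == "STR"] <-
    sample_vec(str_atc_codes(), sum(is_taf & taf_subtype == "STR"))
  atc_index[is_taf & taf_subtype == "MTR"] <-
    sample_vec(c("J05AF13", "J05AR17"), sum(is_taf & taf_subtype == "MTR"))
  atc_index[!is_taf] <- sample_vec(non_taf_pool, sum(!is_taf))

  stop_day <- ifelse(status == "persistent", followup_days,
                     sample_vec(90:240, n))
  stop_day <- pmin(stop_day, followup_days)

  main <- make_refill_days(rep(0L, n), stop_day, target_pdc, supply)
  main$patient_id <- patient_id[main$i]
  main$atc_code <- atc_index[main$i]
  main$date <- index_date[main$i] + main$day
  main$kind <- "art"

  # regimen-class switch: replacement ART from shortly after the stop
  sw <- which(status == "switched")
  sw_start <- stop_day[sw] + sample_vec(15:45, length(sw))
  repl <- make_refill_days(sw_start, followup_days[sw], target_pdc[sw], supply)
  alt_atc <- as.character(ifelse(is_taf[sw],
                                 sample_vec(non_taf_pool, length(sw)),
                                 sample_vec(c("J05AG03", "J05AE08"),
                                            length(sw))))
  repl$patient_id <- patient_id[sw][repl$i]
  repl$atc_code <- alt_atc[repl$i]
  repl$date <- index_date[sw][repl$i] + repl$day
  repl$kind <- "art"

  # switchers to TAF carry prior non-TAF ART through the lookback year
  pre_ids <- which(is_taf & experience == "switcher")
  pre_cap <- pmin(720L, as.integer(index_date[pre_ids] - cfg$study_start))
  pre_len <- 365L + floor(stats::runif(length(pre_ids)) * (pre_cap - 365L + 1L))
  pre <- make_refill_days(-pre_len, rep(0L, length(pre_ids)),
                          rep(0.95, length(pre_ids)), supply)
  pre_atc <- sample_vec(non_taf_pool, length(pre_ids))
  pre$patient_id <- patient_id[pre_ids][pre$i]
  pre$atc_code <- pre_atc[pre$i]
  pre$date <- index_date[pre_ids][pre$i] + pre$day
  pre$kind <- "art"

  # multi-tablet regimens: companion third agent dispensed alongside TAF
  mtr_rows <- main[main$i %in% which(is_taf & taf_subtype == "MTR"), ]
  if (nrow(mtr_rows)) {
    comp_atc <- stats::setNames(sample_vec(companion_pool, n), patient_id)
    mtr_rows$atc_code <- comp_atc[mtr_rows$patient_id]
    mtr_rows$kind <- "companion"
  }

  art_rows <- dplyr::bind_rows(main, repl, pre, mtr_rows)
  art_rows$cost_eur <- ifelse(
    art_rows$kind == "companion",
    rgamma_eur(nrow(art_rows), cfg$cost_params$companion_dispensation),
    rgamma_eur(nrow(art_rows), cfg$cost_params$art_dispensation))

  ## ---- comorbidity trails and other drugs ------------------------------
  set.seed(ss[3])
  cmap <- default_comorbidity_map()
  prev <- cfg$comorbidity_prevalences
  conds <- names(prev)
  flags <- matrix(stats::runif(n * length(conds)) <
                    rep(prev, each = n), n, length(conds),
                  dimnames = list(NULL, conds))

  drug_conds <- conds[vapply(conds, function(k) length(cmap[[k]]$atc) > 0,
                             logical(1))]
  hosp_conds <- setdiff(conds, drug_conds)

  chronic_list <- lapply(drug_conds, function(k) {
    ids <- which(flags[, k])
    if (!length(ids)) return(NULL)
    # guaranteed dispensation in the characterization year, then refills
    # through follow-up at roughly quarterly pace
    base_day <- -360L + floor(stats::runif(length(ids)) * 345)
    extra_n <- stats::rpois(length(ids), followup_days[ids] / 90)
    extra <- tibble::tibble(
      j = rep(seq_along(ids), extra_n),
      day = floor(stats::runif(sum(extra_n)) * rep(followup_days[ids], extra_n)))
    tibble::tibble(
      patient_id = c(patient_id[ids], patient_id[ids][extra$j]),
      atc_code = sample_vec(cmap[[k]]$atc, length(ids) + nrow(extra)),
      date = c(index_date[ids] + base_day,
               index_date[ids][extra$j] + extra$day))
  })
  chronic <- dplyr::bind_rows(chronic_list)

  bg_n <- stats::rpois(n, cfg$other_drug_rate * followup_days / 365.25)
  bg_pool <- c("A02BC02", "M01AE01", "J01CA04", "N02BE01", "B01AC06")
  background <- tibble::tibble(
    patient_id = rep(patient_id, bg_n),
    atc_code = sample_vec(bg_pool, sum(bg_n)),
    date = rep(index_date, bg_n) +
      floor(stats::runif(sum(bg_n)) * rep(followup_days, bg_n)))
  other_drugs <- dplyr::bind_rows(chronic, background)
  if (nrow(other_drugs))
    other_drugs$cost_eur <- rgamma_eur(nrow(other_drugs),
                                       cfg$cost_params$other_dispensation)

  pharmacy <- dplyr::bind_rows(
    tibble::tibble(patient_id = art_rows$patient_id,
                   atc_code = art_rows$atc_code,
                   dispensation_date = art_rows$date,
                   cost_eur = art_rows$cost_eur),
    tibble::tibble(patient_id = other_drugs$patient_id,
                   atc_code = other_drugs$atc_code,
                   dispensation_date = other_drugs$date,
                   cost_eur = other_drugs$cost_eur))
  pharmacy$n_packages <- cfg$n_packages
  pharmacy$units_per_package <- cfg$units_per_package
  pharmacy <- pharmacy[, c("patient_id", "atc_code", "dispensation_date",
                           "n_packages", "units_per_package", "cost_eur")]
  pharmacy <- dplyr::arrange(pharmacy, .data$patient_id,
                             .data$dispensation_date, .data$atc_code)

  ## ---- hospitalizations ------------------------------------------------
  set.seed(ss[4])
  nonpersistent <- status != "persistent"
  # baseline comorbidity admissions (conditions detected via ICD-9 only)
  base_list <- lapply(hosp_conds, function(k) {
    ids <- which(flags[, k])
    if (!length(ids)) return(NULL)
    day <- -360L + floor(stats::runif(length(ids)) * 330)
    tibble::tibble(
      patient_id = patient_id[ids],
      admission_date = index_date[ids] + day,
      icd9_codes = sample_vec(cmap[[k]]$icd9, length(ids)),
      drg_code = sample_vec(default_drg_pool(), length(ids)),
      kind = "other")
  })
  hiv_rate <- ifelse(nonpersistent, cfg$hiv_hosp_rate_nonpersistent,
                     cfg$hiv_hosp_rate_persistent)
  hiv_n <- stats::rpois(n, hiv_rate * followup_days / 365.25)
  hiv_adm <- tibble::tibble(
    patient_id = rep(patient_id, hiv_n),
    admission_date = rep(index_date, hiv_n) +
      floor(stats::runif(sum(hiv_n)) * rep(pmax(followup_days - 10L, 1L), hiv_n)),
    icd9_codes = "042",
    drg_code = sample_vec(hiv_drg_codes(), sum(hiv_n)),
    kind = "hiv")
  oth_n <- stats::rpois(n, cfg$other_hosp_rate * followup_days / 365.25)
  benign_icd9 <- c("540", "550", "574", "715", "722", "780", "786", "820")
  oth_adm <- tibble::tibble(
    patient_id = rep(patient_id, oth_n),
    admission_date = rep(index_date, oth_n) +
      floor(stats::runif(sum(oth_n)) * rep(pmax(followup_days - 10L, 1L), oth_n)),
    icd9_codes = sample_vec(benign_icd9, sum(oth_n)),
    drg_code = sample_vec(default_drg_pool(), sum(oth_n)),
    kind = "other")
  hospital <- dplyr::bind_rows(c(base_list, list(hiv_adm, oth_adm)))
  if (nrow(hospital)) {
    los <- 1L + stats::rpois(nrow(hospital), 5)
    hospital$discharge_date <- pmin(hospital$admission_date + los,
                                    cfg$study_end)
    hospital$tariff_eur <- ifelse(
      hospital$kind == "hiv",
      rgamma_eur(nrow(hospital), cfg$cost_params$hiv_hospitalization),
      rgamma_eur(nrow(hospital), cfg$cost_params$other_hospitalization))
  } else {
    hospital$discharge_date <- as.Date(character())
    hospital$tariff_eur <- numeric()
  }
  hospital <- hospital[, c("patient_id", "admission_date", "discharge_date",
                           "icd9_codes", "drg_code", "tariff_eur")]
  hospital <- dplyr::arrange(hospital, .data$patient_id, .data$admission_date)

  ## ---- outpatient services ---------------------------------------------
  set.seed(ss[5])
  visit_n <- stats::rpois(n, cfg$outpatient_rate * followup_days / 365.25)
  outpatient <- tibble::tibble(
    patient_id = rep(patient_id, visit_n),
    service_date = rep(index_date, visit_n) +
      floor(stats::runif(sum(visit_n)) * rep(followup_days, visit_n)),
    service_type = sample_vec(c("visit", "diagnostic_test"), sum(visit_n)),
    tariff_eur = rgamma_eur(sum(visit_n), cfg$cost_params$outpatient))
  outpatient <- dplyr::arrange(outpatient, .data$patient_id,
                               .data$service_date)

  ground_truth <- tibble::tibble(
    patient_id = patient_id, is_taf = is_taf, taf_subtype = taf_subtype,
    experience = experience, target_pdc = target_pdc, status = status,
    index_date = index_date)

  list(demographics = demographics, pharmacy = pharmacy,
       hospital = hospital, outpatient = outpatient,
       ground_truth = ground_truth)
}

table_filenames <- c(demographics = "demographics.csv",
                     pharmacy = "pharmacy.csv",
                     hospital = "hospital.csv",
                     outpatient = "outpatient.csv",
                     ground_truth = "ground_truth.csv")

#' Write claims tables to CSV
#'
#' Writes `demographics.csv`, `pharmacy.csv`, `hospital.csv`,
#' `outpatient.csv` and, when present, `ground_truth.csv` with ISO-8601
#' dates.
#'
#' @param tables List as returned by [generate_cohort_tables()].
#' @param directory Output directory (created if missing).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_tables <- function(tables, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop("cannot create directory: ", directory, call. = FALSE)
  nms <- intersect(names(table_filenames), names(tables))
  paths <- vapply(nms, function(nm) {
    path <- file.path(directory, table_filenames[[nm]])
    readr::write_csv(tables[[nm]], path, na = "")
    path
  }, character(1))
  invisible(paths)
}

#' Read claims tables from CSV
#'
#' Counterpart of [write_tables()]; restores column types (dates,
#' integers, costs).
#'
#' @param directory Directory containing the CSV files.
#' @return Named list of tibbles (with `ground_truth` when on disk).
#' @export
read_tables <- function(directory) {
  specs <- list(
    demographics = readr::cols(
      patient_id = readr::col_character(), sex = readr::col_character(),
      birth_date = readr::col_date(), enrollment_start = readr::col_date(),
      enrollment_end = readr::col_date(), death_date = readr::col_date(),
      transfer_out = readr::col_logical()),
    pharmacy = readr::cols(
      patient_id = readr::col_character(), atc_code = readr::col_character(),
      dispensation_date = readr::col_date(),
      n_packages = readr::col_integer(),
      units_per_package = readr::col_integer(),
      cost_eur = readr::col_double()),
    hospital = readr::cols(
      patient_id = readr::col_character(),
      admission_date = readr::col_date(), discharge_date = readr::col_date(),
      icd9_codes = readr::col_character(), drg_code = readr::col_character(),
      tariff_eur = readr::col_double()),
    outpatient = readr::cols(
      patient_id = readr::col_character(), service_date = readr::col_date(),
      service_type = readr::col_character(),
      tariff_eur = readr::col_double()),
    ground_truth = readr::cols(
      patient_id = readr::col_character(), is_taf = readr::col_logical(),
      taf_subtype = readr::col_character(),
      experience = readr::col_character(),
      target_pdc = readr::col_double(), status = readr::col_character(),
      index_date = readr::col_date()))
  out <- list()
  for (nm in names(table_filenames)) {
    path <- file.path(directory, table_filenames[[nm]])
    if (nm == "ground_truth" && !file.exists(path)) next
    if (!file.exists(path))
      stop("missing input table: ", path, call. = FALSE)
    out[[nm]] <- readr::read_csv(path, col_types = specs[[nm]],
                                 progress = FALSE)
  }
  out
}
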