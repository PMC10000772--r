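# Cohort construction from the four linked claims tables: screening of
# adult ART users, exclusion rules (single dispensation, refill gap over
# a year, transfer out), TAF index dating, naive/switcher and MTR/STR
# labeling, and baseline characterization over the lookback year.

art_dispensations <- function(pharmacy, spec) {
  pat <- paste0("^(", paste(spec$art_atc_prefixes, collapse = "|"), ")")
  pharmacy[grepl(pat, pharmacy$atc_code), , drop = FALSE]
}

# prefix match of codes against a vector of prefixes
matches_prefix <- function(codes, prefixes) {
  if (!length(prefixes)) return(rep(FALSE, length(codes)))
  pat <- paste0("^(", paste(prefixes, collapse = "|"), ")")
  grepl(pat, codes)
}

#' Screen adult patients on antiretroviral therapy
#'
#' Returns patients with at least one ART dispensation inside the
#' inclusion window who are at least `spec$min_age` years old at their
#' first ART dispensation. Patients without a birth date in demographics
#' are skipped with a warning.
#'
#' @param tables List of claims tibbles (see [generate_cohort_tables()]).
#' @param spec A [cohort_spec()].
#' @return Character vector of patient IDs.
#' @export
screen_art_patients <- function(tables, spec) {
  art <- art_dispensations(tables$pharmacy, spec)
  art <- art[art$dispensation_date >= spec$inclusion_start &
               art$dispensation_date <= spec$inclusion_end, ]
  if (!nrow(art)) return(character())
  first_art <- art |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first_art = min(.data$dispensation_date),
                     .groups = "drop") |>
    dplyr::left_join(tables$demographics[, c("patient_id", "birth_date")],
                     by = "patient_id")
  missing_bd <- is.na(first_art$birth_date)
  if (any(missing_bd)) {
    warning(sum(missing_bd), " screened patient(s) lack a birth date; ",
            "records skipped", call. = FALSE)
    first_art <- first_art[!missing_bd, ]
  }
  age <- as.numeric(first_art$first_art - first_art$birth_date) / 365.25
  sort(first_art$patient_id[age >= spec$min_age])
}

#' Apply cohort exclusion rules
#'
#' Removes screened patients with exactly one ART dispensation overall,
#' any gap between consecutive ART dispensations above
#' `spec$max_gap_days`, or a transfer-out flag in demographics.
#'
#' @inheritParams screen_art_patients
#' @param candidates Patient IDs from [screen_art_patients()].
#' @return List with `keep` (IDs retained) and `excluded` (tibble of
#'   `patient_id`, `reason`).
#' @export
apply_exclusions <- function(candidates, tables, spec) {
  art <- art_dispensations(tables$pharmacy, spec)
  art <- art[art$patient_id %in% candidates, ]
  per <- art |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_disp = dplyr::n(),
      max_gap = if (dplyr::n() > 1)
        max(diff(sort(as.integer(.data$dispensation_date)))) else 0L,
      .groups = "drop")
  transfers <- tables$demographics$patient_id[
    isTRUE_vec(tables$demographics$transfer_out)]
  excluded <- dplyr::bind_rows(
    tibble::tibble(patient_id = per$patient_id[per$n_disp == 1],
                   reason = "single_art_dispensation"),
    tibble::tibble(patient_id = per$patient_id[per$max_gap > spec$max_gap_days],
                   reason = "art_gap_over_limit"),
    tibble::tibble(patient_id = intersect(candidates, transfers),
                   reason = "transfer_out"))
  excluded <- excluded[!duplicated(excluded$patient_id), ]
  list(keep = sort(setdiff(candidates, excluded$patient_id)),
       excluded = excluded)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Index and label the TAF cohort
#'
#' For patients with a TAF dispensation, the index date is the first TAF
#' dispensation; it must fall inside the inclusion window (others are
#' dropped with a message). Experience is `naive` when no ART
#' dispensation occurs in the half-open lookback `[index - lookback,
#' index)` — a dispensation on the index date itself never voids naive
#' status — and `switcher` otherwise. The regimen subtype is `STR` when
#' the first TAF dispensation's ATC belongs to the single-tablet set,
#' else `MTR`, fixed at index. Follow-up runs from index to the earlier
#' of enrollment end and death.
#'
#' @inheritParams screen_art_patients
#' @param patients Patient IDs surviving [apply_exclusions()].
#' @return Tibble with one row per cohort patient: index date, age at
#'   index, both age classifications, sex, subtype, experience,
#'   follow-up end and inclusion year.
#' @export
index_and_label <- function(patients, tables, spec) {
  art <- art_dispensations(tables$pharmacy, spec)
  art <- art[art$patient_id %in% patients, ]
  taf <- art[art$atc_code %in% spec$taf_atc_codes, ]
  if (!nrow(taf)) return(empty_cohort())
  idx <- taf |>
    dplyr::arrange(.data$dispensation_date, .data$atc_code) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(index_date = min(.data$dispensation_date),
                     index_atc = .data$atc_code[
                       which.min(.data$dispensation_date)],
                     .groups = "drop")
  outside <- idx$index_date < spec$inclusion_start |
    idx$index_date > spec$inclusion_end
  if (any(outside)) {
    message(sum(outside), " TAF patient(s) indexed outside the inclusion ",
            "window; excluded")
    idx <- idx[!outside, ]
  }
  if (!nrow(idx)) return(empty_cohort())

  # experience: any ART dispensation strictly before index and within
  # the lookback window
  prior <- art |>
    dplyr::inner_join(idx[, c("patient_id", "index_date")],
                      by = "patient_id") |>
    dplyr::filter(.data$dispensation_date < .data$index_date,
                  .data$dispensation_date >=
                    .data$index_date - spec$lookback_days) |>
    dplyr::distinct(.data$patient_id)
  idx$experience <- ifelse(idx$patient_id %in% prior$patient_id,
                           "switcher", "naive")
  idx$taf_subtype <- ifelse(idx$index_atc %in% spec$str_atc_codes,
                            "STR", "MTR")

  demo <- tables$demographics
  idx <- dplyr::left_join(idx, demo, by = "patient_id")
  data_end <- max(demo$enrollment_end)
  fu_end <- pmin(idx$enrollment_end, data_end)
  dead <- !is.na(idx$death_date)
  fu_end[dead] <- pmin(fu_end, idx$death_date, na.rm = FALSE)[dead]
  idx$followup_end <- fu_end
  idx$age_at_index <- as.numeric(idx$index_date - idx$birth_date) / 365.25
  yrs <- floor(idx$age_at_index)  # completed years, as ages are reported
  idx$age_class <- cut(yrs, c(-Inf, 35, 55, Inf),
                       labels = c("<36", "36-55", ">55"), right = TRUE)
  # the cost-model classification uses 50/65 cut points
  idx$age_class_glm <- cut(yrs, c(-Inf, 50, 65, Inf),
                           labels = c("<=50", "51-65", ">65"), right = TRUE)
  idx$inclusion_year <- as.integer(format(idx$index_date, "%Y"))
  short <- as.integer(idx$followup_end - idx$index_date) <
    spec$min_followup_days & !dead
  if (any(short)) {
    message(sum(short), " TAF patient(s) with follow-up under ",
            spec$min_followup_days, " days and no death; excluded")
    idx <- idx[!short, ]
  }
  tibble::as_tibble(idx[, c("patient_id", "index_date", "index_atc",
                            "age_at_index", "age_class", "age_class_glm",
                            "sex", "taf_subtype", "experience",
                            "followup_end", "inclusion_year")])
}

empty_cohort <- function() {
  tibble::tibble(patient_id = character(),
                 index_date = as.Date(character()),
                 index_atc = character(), age_at_index = numeric(),
                 age_class = factor(character(),
                                    levels = c("<36", "36-55", ">55")),
                 age_class_glm = factor(character(),
                                        levels = c("<=50", "51-65", ">65")),
                 sex = character(), taf_subtype = character(),
                 experience = character(),
                 followup_end = as.Date(character()),
                 inclusion_year = integer())
}

#' Baseline comorbidity profile and modified Charlson score
#'
#' Flags each configured condition when any matching ATC (pharmacy) or
#' ICD-9-CM (hospital discharge) code occurs in the half-open
#' characterization window `[index - lookback, index)`; events on or
#' after the index date are ignored. The Charlson Comorbidity Index is
#' the sum of configured weights over flagged conditions; the HIV item
#' carries no weight by construction, so the score reflects
#' non-HIV comorbidity only.
#'
#' @inheritParams screen_art_patients
#' @param cohort Tibble from [index_and_label()].
#' @return `cohort` with one logical column per condition plus `cci`.
#' @export
characterize_baseline <- function(cohort, tables, spec) {
  cmap <- spec$comorbidity_map
  weights <- spec$cci_weights
  unknown <- setdiff(names(weights), names(cmap))
  if (length(unknown))
    stop("unknown condition in cci weights: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  n <- nrow(cohort)
  flags <- matrix(FALSE, n, length(cmap),
                  dimnames = list(NULL, names(cmap)))
  if (n) {
    ph <- dplyr::inner_join(
      tables$pharmacy[, c("patient_id", "atc_code", "dispensation_date")],
      cohort[, c("patient_id", "index_date")], by = "patient_id")
    ph <- ph[ph$dispensation_date < ph$index_date &
               ph$dispensation_date >= ph$index_date - spec$lookback_days, ]
    ho <- dplyr::inner_join(
      tables$hospital[, c("patient_id", "admission_date", "icd9_codes")],
      cohort[, c("patient_id", "index_date")], by = "patient_id")
    ho <- ho[ho$admission_date < ho$index_date &
               ho$admission_date >= ho$index_date - spec$lookback_days, ]
    # discharge records may carry several codes separated by ";"
    ho_codes <- strsplit(ho$icd9_codes, ";", fixed = TRUE)
    ho_long <- tibble::tibble(
      patient_id = rep(ho$patient_id, lengths(ho_codes)),
      code = trimws(unlist(ho_codes)))
    for (k in names(cmap)) {
      hit <- unique(c(
        ph$patient_id[matches_prefix(ph$atc_code, cmap[[k]]$atc)],
        ho_long$patient_id[matches_prefix(ho_long$code, cmap[[k]]$icd9)]))
      flags[, k] <- cohort$patient_id %in% hit
    }
  }
  out <- dplyr::bind_cols(cohort, tibble::as_tibble(flags))
  w <- stats::setNames(rep(0L, length(cmap)), names(cmap))
  w[names(weights)] <- weights
  out$cci <- as.integer(flags %*% w)
  out
}

#' Build the TAF cohort end to end
#'
#' Runs screening, exclusions, indexing/labeling and baseline
#' characterization, returning both the cohort and an attrition record.
#'
#' @inheritParams screen_art_patients
#' @return List with `cohort` (tibble), `screened` (IDs),
#'   `excluded` (tibble of ID/reason), and `attrition` (stage counts).
#' @export
build_cohort <- function(tables, spec = cohort_spec()) {
  screened <- screen_art_patients(tables, spec)
  excl <- apply_exclusions(screened, tables, spec)
  cohort <- index_and_label(excl$keep, tables, spec)
  cohort <- characterize_baseline(cohort, tables, spec)
  list(cohort = cohort,
       screened = screened,
       excluded = excl$excluded,
       attrition = tibble::tibble(
         stage = c("screened", "after_exclusions", "taf_cohort"),
         n = c(length(screened), length(excl$keep), nrow(cohort))))
}
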