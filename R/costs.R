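# Annualized healthcare resource counts and direct costs per patient,
# split into the five cost items (HIV drugs, other drugs, HIV
# hospitalizations, other hospitalizations, outpatient services), with
# the mean + 3 SD outlier rule and stratified summaries. Money is
# handled in integer euro cents internally.

cost_items <- function() c("hiv_drugs", "other_drugs", "hiv_hosp",
                           "other_hosp", "outpatient")

#' Annualized resource use and costs per patient
#'
#' For each cohort patient, classifies every event in the analysis
#' window — drug dispensations are HIV-related when the ATC belongs to
#' the ART class, hospitalizations when the DRG is 488, 489 or 490 —
#' and annualizes counts and costs by the person-years of the window.
#' The first-year window is a fixed 365-day period from index with one
#' person-year; the all-follow-up window runs to the end of follow-up
#' with person-years `days / 365.25`. Following the alive-patient rule,
#' patients dead before the end of the analysis window are excluded.
#' DRGs outside the configured dictionary are counted as other-cause
#' admissions with a note.
#'
#' @param tables Claims tables list.
#' @param cohort Cohort tibble from [build_cohort()].
#' @param spec A [cohort_spec()].
#' @param window `"first_year"` or `"all_followup"`.
#' @return Tibble with per-patient annualized counts (`n_*`) and costs
#'   in EUR (`cost_*`, with `cost_total` the sum of the five items).
#' @export
tally_resources <- function(tables, cohort, spec = cohort_spec(),
                            window = c("first_year", "all_followup")) {
  window <- match.arg(window)
  demo <- tables$demographics[, c("patient_id", "death_date")]
  coh <- dplyr::left_join(cohort, demo, by = "patient_id")
  if (window == "first_year") {
    alive <- is.na(coh$death_date) | coh$death_date >= coh$index_date + 365L
    coh <- coh[alive, ]
    win_end <- coh$index_date + 365L
    py <- rep(1, nrow(coh))
  } else {
    coh <- coh[is.na(coh$death_date), ]
    win_end <- coh$followup_end
    py <- as.numeric(win_end - coh$index_date) / 365.25
  }
  if (any(py <= 0)) {
    coh <- coh[py > 0, ]; win_end <- win_end[py > 0]; py <- py[py > 0]
  }
  base <- tibble::tibble(patient_id = coh$patient_id,
                         index_date = coh$index_date,
                         win_end = win_end, person_years = py)

  in_window <- function(df, date_col) {
    df <- dplyr::inner_join(df, base, by = "patient_id")
    df[df[[date_col]] >= df$index_date & df[[date_col]] < df$win_end, ]
  }

  ph <- in_window(tables$pharmacy, "dispensation_date")
  ph$cents <- as.integer(round(ph$cost_eur * 100))
  ph$hiv_related <- matches_prefix(ph$atc_code, spec$art_atc_prefixes)
  ph_sum <- ph |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_hiv_drug_disp = sum(.data$hiv_related),
      n_other_drug_disp = sum(!.data$hiv_related),
      cents_hiv_drugs = sum(.data$cents[.data$hiv_related]),
      cents_other_drugs = sum(.data$cents[!.data$hiv_related]),
      .groups = "drop")

  ho <- in_window(tables$hospital, "admission_date")
  ho$cents <- as.integer(round(ho$tariff_eur * 100))
  unknown <- !(ho$drg_code %in% spec$drg_dictionary)
  if (any(unknown))
    message(sum(unknown), " admission(s) with DRG outside the configured ",
            "dictionary counted as other-cause")
  ho$hiv_related <- ho$drg_code %in% hiv_drg_codes()
  ho_sum <- ho |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_hiv_hosp = sum(.data$hiv_related),
      n_other_hosp = sum(!.data$hiv_related),
      cents_hiv_hosp = sum(.data$cents[.data$hiv_related]),
      cents_other_hosp = sum(.data$cents[!.data$hiv_related]),
      .groups = "drop")

  ou <- in_window(tables$outpatient, "service_date")
  ou$cents <- as.integer(round(ou$tariff_eur * 100))
  ou_sum <- ou |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_outpatient = dplyr::n(),
                     cents_outpatient = sum(.data$cents),
                     .groups = "drop")

  out <- base |>
    dplyr::left_join(ph_sum, by = "patient_id") |>
    dplyr::left_join(ho_sum, by = "patient_id") |>
    dplyr::left_join(ou_sum, by = "patient_id")
  for (cl in setdiff(names(out), c("patient_id", "index_date", "win_end",
                                   "person_years")))
    out[[cl]][is.na(out[[cl]])] <- 0
  out$window <- window
  for (it in c("n_hiv_drug_disp", "n_other_drug_disp", "n_hiv_hosp",
               "n_other_hosp", "n_outpatient"))
    out[[it]] <- out[[it]] / out$person_years
  items <- cost_items()
  for (it in items)
    out[[paste0("cost_", it)]] <-
      out[[paste0("cents_", it)]] / 100 / out$person_years
  out$cost_total <- rowSums(as.matrix(out[paste0("cost_", items)]))
  out[, c("patient_id", "window", "person_years",
          "n_hiv_drug_disp", "n_other_drug_disp", "n_hiv_hosp",
          "n_other_hosp", "n_outpatient",
          paste0("cost_", items), "cost_total")]
}

#' Exclude cost outliers
#'
#' Single pass over the analysis population: computes the mean and
#' sample standard deviation of the per-patient total cost and drops
#' patients whose total is strictly above mean + 3 SD. The rule is not
#' re-iterated and not re-applied within strata.
#'
#' @param breakdowns Tibble from [tally_resources()].
#' @return List with `retained` (tibble), `excluded_ids` (character)
#'   and `threshold` (EUR).
#' @export
exclude_outliers <- function(breakdowns) {
  if (nrow(breakdowns) < 2) {
    warning("fewer than 2 patients: no outlier exclusion applied",
            call. = FALSE)
    return(list(retained = breakdowns, excluded_ids = character(),
                threshold = Inf))
  }
  m <- mean(breakdowns$cost_total)
  s <- stats::sd(breakdowns$cost_total)
  threshold <- m + 3 * s
  out <- breakdowns$cost_total > threshold
  list(retained = breakdowns[!out, ],
       excluded_ids = breakdowns$patient_id[out],
       threshold = threshold)
}

#' Stratified cost table
#'
#' Mean and standard deviation of each annualized cost item by stratum,
#' with Welch two-sample comparisons per item when exactly two strata
#' are present. Outlier exclusion (when wanted) is applied by the
#' caller before stratification. Empty strata are omitted.
#'
#' @param breakdowns Tibble from [tally_resources()] (after any outlier
#'   exclusion).
#' @param labels Tibble with `patient_id` and `stratum` covering the
#'   retained patients.
#' @param compare Whether to run two-group comparisons (only when the
#'   label has exactly two levels).
#' @return List with `summary` (one row per stratum and cost item:
#'   `n`, `mean`, `sd`) and `comparisons` (per-item difference and
#'   Welch p-value, or `NULL`).
#' @export
stratify_costs <- function(breakdowns, labels, compare = TRUE) {
  df <- dplyr::inner_join(breakdowns, labels, by = "patient_id")
  uncovered <- setdiff(breakdowns$patient_id, labels$patient_id)
  if (length(uncovered))
    warning(length(uncovered), " patient(s) without a stratum label ",
            "omitted", call. = FALSE)
  cols <- c(paste0("cost_", cost_items()), "cost_total")
  summary <- df |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "item",
                        values_to = "value") |>
    dplyr::group_by(.data$stratum, .data$item) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop")
  comparisons <- NULL
  strata <- unique(df$stratum)
  if (compare && length(strata) == 2) {
    a <- df[df$stratum == strata[1], ]
    b <- df[df$stratum == strata[2], ]
    comparisons <- dplyr::bind_rows(lapply(cols, function(cl) {
      cmp <- compare_groups(a[[cl]], b[[cl]])
      tibble::tibble(item = cl,
                     group_a = as.character(strata[1]),
                     group_b = as.character(strata[2]),
                     mean_a = mean(a[[cl]]), mean_b = mean(b[[cl]]),
                     difference = cmp$difference, p_value = cmp$p_value)
    }))
  }
  list(summary = summary, comparisons = comparisons)
}
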