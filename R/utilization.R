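# Coverage timelines, proportion of days covered (PDC), adherence
# thresholds, and the persistence / switch / discontinuation
# classification. Day arithmetic is half-open throughout: day 0 is the
# index date, an interval [start, end) covers days start..end-1.

# Carry-forward coverage: each dispensation supplies `supply` days; an
# early refill starts when the previous supply runs out, so overlapping
# supply is stockpiled rather than discarded. Given day offsets and
# per-dispensation supplies, returns interval starts/ends before window
# truncation. end_k = S_k + max_{j<=k}(day_j - S_{j-1}) with S the
# cumulative supply, which equals the sequential recursion
# end_k = max(day_k, end_{k-1}) + s_k.
coverage_intervals <- function(day, supply) {
  o <- order(day)
  d <- day[o]; s <- supply[o]
  S <- cumsum(as.numeric(s))
  end <- S + cummax(d - c(0, S[-length(S)]))
  start <- pmax(d, c(0, end[-length(end)]))
  list(start = start, end = end)
}

# Total covered days inside [0, window).
covered_days <- function(day, supply, window) {
  if (!length(day)) return(0)
  iv <- coverage_intervals(day, supply)
  sum(pmin(iv$end, window) - pmin(iv$start, window))
}

#' Build a therapy-coverage timeline for one patient
#'
#' Converts a stream of dispensations into a disjoint union of
#' half-open day intervals relative to the index date. Each
#' dispensation contributes `n_packages * units_per_package` days of
#' supply (one unit is one day of therapy under once-daily dosing);
#' early refills carry forward. Coverage is truncated at the window
#' end. Dispensations dated before the index are ignored with a
#' warning.
#'
#' @param dispensations Tibble with `dispensation_date`, `n_packages`,
#'   `units_per_package` (already restricted to the drug scope of
#'   interest).
#' @param index_date Index date (day 0).
#' @param window_days Length of the observation window in days.
#' @return Object of class `coverage_timeline`: list with `intervals`
#'   (tibble of `start`, `end`), `window_days` and `covered_days`.
#' @export
build_coverage <- function(dispensations, index_date, window_days) {
  if (window_days <= 0)
    stop("`window_days` must be positive", call. = FALSE)
  day <- as.integer(dispensations$dispensation_date - as.Date(index_date))
  supply <- dispensations$n_packages * dispensations$units_per_package
  pre <- day < 0
  if (any(pre)) {
    warning(sum(pre), " dispensation(s) before the index date ignored",
            call. = FALSE)
    day <- day[!pre]; supply <- supply[!pre]
  }
  if (!length(day)) {
    iv <- tibble::tibble(start = integer(), end = integer())
    return(structure(list(intervals = iv, window_days = window_days,
                          covered_days = 0), class = "coverage_timeline"))
  }
  iv <- coverage_intervals(day, supply)
  start <- pmin(iv$start, window_days)
  end <- pmin(iv$end, window_days)
  keep <- end > start
  start <- start[keep]; end <- end[keep]
  # merge touching intervals into a normalized disjoint union
  if (length(start) > 1) {
    new_run <- c(TRUE, start[-1] > end[-length(end)])
    grp <- cumsum(new_run)
    start <- tapply(start, grp, min)
    end <- tapply(end, grp, max)
  }
  structure(list(
    intervals = tibble::tibble(start = as.integer(start),
                               end = as.integer(end)),
    window_days = window_days,
    covered_days = sum(end - start)), class = "coverage_timeline")
}

#' Proportion of days covered
#'
#' PDC is 100 times covered days over window days, capped at 100.
#'
#' @param timeline A `coverage_timeline` from [build_coverage()].
#' @return PDC as a percentage in `[0, 100]`.
#' @export
compute_pdc <- function(timeline) {
  if (!inherits(timeline, "coverage_timeline"))
    stop("`timeline` must be a coverage_timeline", call. = FALSE)
  if (timeline$window_days == 0)
    stop("undefined PDC: window has zero days", call. = FALSE)
  min(100, 100 * timeline$covered_days / timeline$window_days)
}

#' Classify adherence from PDC
#'
#' Applies the two adherence thresholds (strictly greater than 95 and
#' than 85) and assigns the reporting stratum: `<80` for PDC at or
#' below 80, `81-95` for PDC in (80, 95], `>95` above 95.
#'
#' @param pdc Numeric vector of PDC percentages in `[0, 100]`.
#' @return Tibble with `adherent_95`, `adherent_85`,
#'   `adherence_stratum`.
#' @export
classify_adherence <- function(pdc) {
  if (any(!is.finite(pdc)) || any(pdc < 0) || any(pdc > 100))
    stop("PDC values must lie in [0, 100]", call. = FALSE)
  stratum <- cut(pdc, c(-Inf, 80, 95, Inf),
                 labels = c("<80", "81-95", ">95"), right = TRUE)
  tibble::tibble(adherent_95 = pdc > 95,
                 adherent_85 = pdc > 85,
                 adherence_stratum = stratum)
}

# Evaluation window for persistence/discontinuation: the last quarter of
# an F-day follow-up is [F - floor(F/4), F). For the default 365-day
# first year this is days [274, 365).
last_quarter_window <- function(followup) {
  cbind(start = followup - floor(followup / 4), end = followup)
}

#' Persistence, switch and discontinuation for one patient
#'
#' Evaluates the last quarter of the first follow-up year (days
#' `[274, 365)` after index for a full year): `discontinued` when no
#' ART dispensation falls in the window, otherwise `persistent` when a
#' TAF-class dispensation does, otherwise `switched` (with the switch
#' date set to the first non-TAF ART dispensation after the last TAF
#' dispensation). Follow-up shorter than a year (death) truncates the
#' window to the last quarter of the available follow-up and flags the
#' result as censored.
#'
#' @param dispensations Tibble of the patient's ART dispensations
#'   (`atc_code`, `dispensation_date`, `n_packages`,
#'   `units_per_package`).
#' @param index_date Index date.
#' @param followup_end End of follow-up (enrollment end or death).
#' @param spec A [cohort_spec()] (for TAF/ART code sets).
#' @param persistence_rule `"date_in_window"` (default: a dispensation
#'   date inside the window) or `"coverage_in_window"` (supply coverage
#'   overlapping the window).
#' @param window_basis `"first_year"` (default) or `"all_followup"` for
#'   the follow-up length whose last quarter is evaluated.
#' @return One-row tibble: `persistent_taf`, `persistent_any_art`,
#'   `status`, `switch_date`, `censored`.
#' @export
classify_status <- function(dispensations, index_date, followup_end,
                            spec = cohort_spec(),
                            persistence_rule = c("date_in_window",
                                                 "coverage_in_window"),
                            window_basis = c("first_year", "all_followup")) {
  persistence_rule <- match.arg(persistence_rule)
  window_basis <- match.arg(window_basis)
  art <- dispensations[matches_prefix(dispensations$atc_code,
                                      spec$art_atc_prefixes), ]
  day <- as.integer(art$dispensation_date - as.Date(index_date))
  is_taf_code <- art$atc_code %in% spec$taf_atc_codes
  fu <- as.integer(as.Date(followup_end) - as.Date(index_date))
  eval_fu <- if (window_basis == "first_year") min(fu, 365L) else fu
  w <- last_quarter_window(eval_fu)
  in_w <- function(keep) {
    if (persistence_rule == "date_in_window") {
      any(day[keep] >= w[, "start"] & day[keep] < w[, "end"])
    } else {
      post <- keep & day >= 0
      cov_end <- covered_days(day[post],
                              (art$n_packages * art$units_per_package)[post],
                              w[, "end"])
      cov_start <- covered_days(day[post],
                                (art$n_packages * art$units_per_package)[post],
                                w[, "start"])
      (cov_end - cov_start) > 0
    }
  }
  persistent_taf <- in_w(is_taf_code)
  persistent_any <- in_w(rep(TRUE, length(day)))
  status <- if (!persistent_any) "discontinued"
    else if (persistent_taf) "persistent" else "switched"
  switch_date <- as.Date(NA)
  if (status == "switched") {
    last_taf <- suppressWarnings(max(art$dispensation_date[is_taf_code]))
    cand <- art$dispensation_date[!is_taf_code &
                                    art$dispensation_date > last_taf]
    if (length(cand)) switch_date <- min(cand)
  }
  tibble::tibble(persistent_taf = persistent_taf,
                 persistent_any_art = persistent_any,
                 status = status, switch_date = switch_date,
                 censored = fu < 365L)
}

#' Per-patient drug utilization for a cohort
#'
#' Computes TAF-scope PDC over a fixed window from index, the adherence
#' flags and stratum, and the persistence / switch / discontinuation
#' classification for every cohort patient, fully vectorized.
#'
#' @inheritParams classify_status
#' @param tables Claims tables list.
#' @param cohort Cohort tibble from [build_cohort()].
#' @param window_days PDC denominator in days (default 365, the
#'   first-year analysis window); `NULL` uses each patient's full
#'   follow-up length.
#' @param pdc_scope `"TAF"` (default) or `"any_art"`: which
#'   dispensations count as coverage.
#' @return Tibble with one row per patient (see [classify_status()] and
#'   [classify_adherence()] for the fields).
#' @export
compute_utilization <- function(tables, cohort, spec = cohort_spec(),
                                window_days = 365L,
                                pdc_scope = c("TAF", "any_art"),
                                persistence_rule = c("date_in_window",
                                                     "coverage_in_window"),
                                window_basis = c("first_year",
                                                 "all_followup")) {
  pdc_scope <- match.arg(pdc_scope)
  persistence_rule <- match.arg(persistence_rule)
  window_basis <- match.arg(window_basis)
  if (!nrow(cohort))
    return(tibble::tibble(patient_id = character(), pdc = numeric(),
                          adherent_95 = logical(), adherent_85 = logical(),
                          adherence_stratum = factor(levels =
                            c("<80", "81-95", ">95")),
                          persistent_taf = logical(),
                          persistent_any_art = logical(),
                          status = character(),
                          switch_date = as.Date(character()),
                          censored = logical()))
  art <- art_dispensations(tables$pharmacy, spec)
  art <- dplyr::inner_join(
    art, cohort[, c("patient_id", "index_date", "followup_end")],
    by = "patient_id")
  art$day <- as.integer(art$dispensation_date - art$index_date)
  art$supply <- art$n_packages * art$units_per_package
  art$is_taf_code <- art$atc_code %in% spec$taf_atc_codes
  art$fu <- as.integer(art$followup_end - art$index_date)

  fu_all <- as.integer(cohort$followup_end - cohort$index_date)
  win <- if (is.null(window_days)) fu_all else rep(as.integer(window_days),
                                                   nrow(cohort))
  names(win) <- cohort$patient_id

  # PDC in the fixed window
  cov <- art[art$day >= 0 &
               (if (pdc_scope == "TAF") art$is_taf_code else TRUE), ] |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(covered = covered_days(.data$day, .data$supply,
                                            win[[.data$patient_id[1]]]),
                     .groups = "drop")
  res <- tibble::tibble(patient_id = cohort$patient_id,
                        window_days = win, fu = fu_all)
  res <- dplyr::left_join(res, cov, by = "patient_id")
  res$covered[is.na(res$covered)] <- 0
  res$pdc <- pmin(100, 100 * res$covered / res$window_days)
  res <- dplyr::bind_cols(res, classify_adherence(res$pdc))

  # last-quarter evaluation window
  eval_fu <- if (window_basis == "first_year") pmin(fu_all, 365L) else fu_all
  wq <- last_quarter_window(eval_fu)
  wtab <- tibble::tibble(patient_id = cohort$patient_id,
                         w_start = wq[, "start"], w_end = wq[, "end"])
  art <- dplyr::left_join(art, wtab, by = "patient_id")
  if (persistence_rule == "date_in_window") {
    st <- art |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        persistent_taf = any(.data$is_taf_code & .data$day >= .data$w_start &
                               .data$day < .data$w_end),
        persistent_any_art = any(.data$day >= .data$w_start &
                                   .data$day < .data$w_end),
        .groups = "drop")
  } else {
    st <- art |>
      dplyr::filter(.data$day >= 0) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        persistent_taf =
          (covered_days(.data$day[.data$is_taf_code],
                        .data$supply[.data$is_taf_code],
                        .data$w_end[1]) -
           covered_days(.data$day[.data$is_taf_code],
                        .data$supply[.data$is_taf_code],
                        .data$w_start[1])) > 0,
        persistent_any_art =
          (covered_days(.data$day, .data$supply, .data$w_end[1]) -
           covered_days(.data$day, .data$supply, .data$w_start[1])) > 0,
        .groups = "drop")
  }
  sw <- art |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(switch_date = {
      lt <- suppressWarnings(max(.data$dispensation_date[.data$is_taf_code]))
      cand <- .data$dispensation_date[!.data$is_taf_code &
                                        .data$dispensation_date > lt]
      if (length(cand)) min(cand) else as.Date(NA)
    }, .groups = "drop")
  res <- res |>
    dplyr::left_join(st, by = "patient_id") |>
    dplyr::left_join(sw, by = "patient_id")
  res$persistent_taf[is.na(res$persistent_taf)] <- FALSE
  res$persistent_any_art[is.na(res$persistent_any_art)] <- FALSE
  res$status <- ifelse(!res$persistent_any_art, "discontinued",
                       ifelse(res$persistent_taf, "persistent", "switched"))
  res$switch_date[res$status != "switched"] <- as.Date(NA)
  res$censored <- res$fu < 365L
  res |>
    dplyr::rename(covered_days = "covered") |>
    dplyr::select("patient_id", "pdc", "covered_days", "window_days",
                  "adherent_95", "adherent_85", "adherence_stratum",
                  "persistent_taf", "persistent_any_art", "status",
                  "switch_date", "censored")
}

#' Cohort-level utilization summary
#'
#' Proportions (percent) of patients adherent at both thresholds,
#' persistent to TAF and to any ART, switched and discontinued —
#' overall and, when the cohort is supplied, by regimen subtype and
#' treatment experience.
#'
#' @param results Tibble from [compute_utilization()].
#' @param cohort Optional cohort tibble providing `taf_subtype` and
#'   `experience` for subgroup rows.
#' @return Tibble with one row per group.
#' @export
summarize_utilization <- function(results, cohort = NULL) {
  if (!nrow(results)) return(tibble::tibble())
  one <- function(df, label) {
    tibble::tibble(
      group = label, n = nrow(df),
      pct_adherent_95 = 100 * mean(df$adherent_95),
      pct_adherent_85 = 100 * mean(df$adherent_85),
      pct_persistent_taf = 100 * mean(df$persistent_taf),
      pct_persistent_any_art = 100 * mean(df$persistent_any_art),
      pct_persistent = 100 * mean(df$status == "persistent"),
      pct_switched = 100 * mean(df$status == "switched"),
      pct_discontinued = 100 * mean(df$status == "discontinued"))
  }
  out <- one(results, "overall")
  if (!is.null(cohort)) {
    joined <- dplyr::inner_join(
      results, cohort[, c("patient_id", "taf_subtype", "experience")],
      by = "patient_id")
    for (col in c("taf_subtype", "experience")) {
      for (lv in sort(unique(joined[[col]]))) {
        out <- dplyr::bind_rows(out, one(joined[joined[[col]] == lv, ], lv))
      }
    }
  }
  out
}
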