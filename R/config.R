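#' ATC codes of TAF-containing regimens
#'
#' Tenofovir alafenamide (TAF) is marketed alone (J05AF13), as the
#' FTC/TAF backbone (J05AR17) and in four complete fixed-dose
#' combinations (J05AR18, J05AR19, J05AR20, J05AR22).
#'
#' @return Character vector of ATC codes.
#' @export
taf_atc_codes <- function() {
  c("J05AF13", "J05AR17", "J05AR18", "J05AR19", "J05AR20", "J05AR22")
}

#' ATC codes of TAF single-tablet regimens
#'
#' The four fixed-dose combinations that are complete regimens in one
#' tablet (STR). TAF alone and the FTC/TAF backbone require concomitant
#' third agents and are treated as multi-tablet regimens (MTR).
#'
#' @return Character vector of ATC codes (subset of [taf_atc_codes()]).
#' @export
str_atc_codes <- function() {
  c("J05AR18", "J05AR19", "J05AR20", "J05AR22")
}

#' HIV-related hospitalization DRG codes
#' @return Character vector `c("488", "489", "490")`.
#' @export
hiv_drg_codes <- function() c("488", "489", "490")

# DRGs accepted for non-HIV admissions in the bundled generator; also the
# default DRG dictionary of the cost tally (unknown DRGs are counted as
# other-cause admissions with a note).
default_drg_pool <- function() c("089", "127", "183", "243", "359", "494")

#' Default comorbidity code map
#'
#' Condition -> list of ATC prefixes and ICD-9-CM prefixes used to flag the
#' condition during the 12-month characterization period. The map is
#' configuration, not a fixed fact: real deployments substitute their own
#' validated code lists. Prefix matching is used on both coding systems.
#'
#' @return Named list; each element has character vectors `atc` and `icd9`.
#' @export
default_comorbidity_map <- function() {
  list(
    depression = list(
      atc = c("N06A"), icd9 = c("296", "3004", "311")),
    respiratory_disease = list(
      atc = c("R03"), icd9 = as.character(490:496)),
    renal_failure = list(
      atc = character(), icd9 = c("584", "585", "586")),
    alcohol_drug_abuse = list(
      atc = c("N07BB", "N07BC"), icd9 = as.character(c(291, 292, 303, 304, 305))),
    cardiovascular_disease = list(
      atc = character(), icd9 = as.character(c(410:414, 428))),
    cancer = list(
      atc = c("L01"), icd9 = as.character(c(140:172, 174:195, 200:208))),
    metastatic_cancer = list(
      atc = character(), icd9 = as.character(196:199)),
    diabetes = list(
      atc = c("A10"), icd9 = c("250")),
    dyslipidemia = list(
      atc = c("C10"), icd9 = c("272")),
    hbv_hcv = list(
      atc = character(), icd9 = c("070")),
    hypertension = list(
      atc = c("C02", "C03", "C09"), icd9 = as.character(401:405))
  )
}

#' Default Charlson weights (HIV item excluded)
#'
#' Deyo-style integer weights for the conditions of
#' [default_comorbidity_map()] that enter the Charlson Comorbidity Index.
#' The HIV/AIDS item is deliberately absent: the score is a modified CCI
#' that does not count HIV itself, since every cohort member carries it.
#' Conditions listed in the comorbidity map but not here carry weight 0.
#'
#' @return Named integer vector of weights.
#' @export
default_cci_weights <- function() {
  c(respiratory_disease = 1L,
    cardiovascular_disease = 1L,
    diabetes = 1L,
    hbv_hcv = 1L,          # mild liver disease
    renal_failure = 2L,
    cancer = 2L,
    metastatic_cancer = 6L)
}

#' Cohort construction specification
#'
#' Holds every rule used to screen, include and characterize patients:
#' the ART ATC prefix, the TAF and STR code sets, the inclusion window,
#' minimum age, lookback and follow-up lengths, the maximum allowed gap
#' between consecutive ART dispensations, and the comorbidity / Charlson
#' configuration.
#'
#' @param art_atc_prefixes ATC prefixes identifying ART (default `"J05A"`).
#' @param taf_atc_codes,str_atc_codes TAF and single-tablet-regimen code
#'   sets; `str_atc_codes` must be a subset of `taf_atc_codes`.
#' @param inclusion_start,inclusion_end Index-date inclusion window.
#' @param min_age Minimum age in years at first ART dispensation.
#' @param lookback_days Characterization period length before index.
#' @param max_gap_days Maximum gap between consecutive ART dispensations
#'   before a patient is excluded.
#' @param min_followup_days Required follow-up after index unless death.
#' @param comorbidity_map Condition code map, see [default_comorbidity_map()].
#' @param cci_weights Charlson weights, see [default_cci_weights()].
#' @param drg_dictionary Known DRG codes (HIV DRGs are always known).
#' @return A list with class `cohort_spec`.
#' @export
cohort_spec <- function(art_atc_prefixes = "J05A",
                        taf_atc_codes = artclaims::taf_atc_codes(),
                        str_atc_codes = artclaims::str_atc_codes(),
                        inclusion_start = as.Date("2015-01-01"),
                        inclusion_end = as.Date("2019-12-31"),
                        min_age = 18,
                        lookback_days = 365L,
                        max_gap_days = 365L,
                        min_followup_days = 365L,
                        comorbidity_map = default_comorbidity_map(),
                        cci_weights = default_cci_weights(),
                        drg_dictionary = c(hiv_drg_codes(), default_drg_pool())) {
  if (!all(str_atc_codes %in% taf_atc_codes))
    stop("`str_atc_codes` must be a subset of `taf_atc_codes`", call. = FALSE)
  if (lookback_days <= 0 || max_gap_days <= 0 || min_followup_days <= 0)
    stop("lookback, gap and follow-up lengths must be positive", call. = FALSE)
  inclusion_start <- as.Date(inclusion_start)
  inclusion_end <- as.Date(inclusion_end)
  if (inclusion_start >= inclusion_end)
    stop("`inclusion_start` must precede `inclusion_end`", call. = FALSE)
  unknown <- setdiff(names(cci_weights), names(comorbidity_map))
  if (length(unknown))
    stop("cci_weights name conditions absent from comorbidity_map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(
    art_atc_prefixes = art_atc_prefixes,
    taf_atc_codes = taf_atc_codes,
    str_atc_codes = str_atc_codes,
    inclusion_start = inclusion_start,
    inclusion_end = inclusion_end,
    min_age = min_age,
    lookback_days = as.integer(lookback_days),
    max_gap_days = as.integer(max_gap_days),
    min_followup_days = as.integer(min_followup_days),
    comorbidity_map = comorbidity_map,
    cci_weights = cci_weights,
    drg_dictionary = drg_dictionary
  ), class = "cohort_spec")
}

#' Mixture specification for per-patient target PDC
#'
#' A mixture of uniform components over `[0, 1]`: patient-level target
#' adherence is drawn by picking a component with probability `weights`
#' and then a uniform value on `[lower, upper]` of that component.
#'
#' @param weights Component probabilities (normalized internally).
#' @param lower,upper Component bounds in `[0, 1]`, `lower <= upper`.
#' @return A list with class `pdc_mixture`.
#' @export
pdc_mixture <- function(weights, lower, upper) {
  stopifnot(length(weights) == length(lower), length(lower) == length(upper))
  if (any(weights < 0) || sum(weights) <= 0)
    stop("mixture weights must be non-negative and sum to > 0", call. = FALSE)
  if (any(lower < 0) || any(upper > 1) || any(lower > upper))
    stop("mixture components must satisfy 0 <= lower <= upper <= 1", call. = FALSE)
  structure(list(weights = weights / sum(weights), lower = lower, upper = upper),
            class = "pdc_mixture")
}

# Draw n target-PDC values from a mixture spec.
sample_pdc_targets <- function(mix, n) {
  stopifnot(inherits(mix, "pdc_mixture"))
  k <- sample.int(length(mix$weights), n, replace = TRUE, prob = mix$weights)
  stats::runif(n, mix$lower[k], mix$upper[k])
}

# Default adherence mix: most patients near-complete coverage, a middle
# band, and a small poorly-covered tail, emulating the observed adherence
# distribution of TAF-treated patients.
default_pdc_mixture <- function() {
  pdc_mixture(weights = c(0.84, 0.10, 0.06),
              lower = c(0.96, 0.86, 0.60),
              upper = c(1.00, 0.95, 0.84))
}

# Per-item gamma cost parameters (EUR). Means: ART pack ~600/dispensation
# (ART ends up near 70% of total annual spend), companion third agents
# ~250, other drugs ~35/dispensation, HIV admission ~4500, other admission
# ~3000, outpatient service ~60.
default_cost_params <- function() {
  list(art_dispensation   = c(shape = 60, scale = 10),
       companion_dispensation = c(shape = 25, scale = 10),
       other_dispensation = c(shape = 2, scale = 17.5),
       hiv_hospitalization = c(shape = 4, scale = 1125),
       other_hospitalization = c(shape = 3, scale = 1000),
       outpatient          = c(shape = 3, scale = 20))
}

#' Synthetic-claims generator configuration
#'
#' Defines the statistical conditions the generator emulates: the
#' demographic mix, comorbidity prevalences, TAF regimen mix
#' (MTR/STR, naive/switcher shares), the per-patient target-PDC mixture
#' driving the refill-gap process, persistence/switch/discontinuation
#' shares, persistence-dependent HIV hospitalization rates, and
#' gamma-distributed cost components. Defaults reproduce the margins of
#' the reference cohort (2658 ART patients, 71.6% male, mean age 48.6,
#' 45.1% on TAF of whom 57.1% STR and 39.9% naive, 78.5% persistent).
#'
#' @param n_patients Number of patients to simulate.
#' @param male_fraction Probability of male sex.
#' @param age_mean,age_sd Age-at-index distribution (years), truncated to
#'   `[18, 95]`.
#' @param comorbidity_prevalences Named probabilities per condition; names
#'   must exist in [default_comorbidity_map()].
#' @param taf_fraction Probability an ART patient is on a TAF regimen.
#' @param str_fraction_given_taf,naive_fraction_given_taf Conditional
#'   shares of single-tablet regimens and of treatment-naive patients
#'   among TAF users.
#' @param pdc_target_distribution A [pdc_mixture()] for per-patient target
#'   adherence.
#' @param persistence_prob,switch_prob Shares of patients remaining on
#'   the index regimen through the first year vs switching regimen class;
#'   the remainder discontinue. Must sum to at most 1.
#' @param n_packages,units_per_package Dispensed pack structure; one unit
#'   is one day of therapy (once-daily dosing), so days supplied per
#'   dispensation is `n_packages * units_per_package`.
#' @param cost_params Named list of `c(shape, scale)` gamma parameters in
#'   EUR per cost component, see `default_cost_params()`.
#' @param hiv_hosp_rate_persistent,hiv_hosp_rate_nonpersistent HIV-related
#'   admission rates (events per person-year) by persistence label.
#' @param other_hosp_rate,outpatient_rate,other_drug_rate Background
#'   utilization rates per person-year.
#' @param death_prob,transfer_prob Probability of death after the first
#'   follow-up year and of transfer to another health unit (transfers are
#'   flagged in demographics and excluded downstream).
#' @param study_start,study_end Data availability window; every generated
#'   event date falls inside it.
#' @param inclusion_start,inclusion_end Window for index dates; capped so
#'   each patient has at least one year of follow-up.
#' @param seed Integer seed; all randomness derives from it.
#' @return A list with class `claims_config`.
#' @export
claims_config <- function(n_patients = 2658,
                          male_fraction = 0.716,
                          age_mean = 48.6,
                          age_sd = 11.0,
                          comorbidity_prevalences = c(
                            depression = 0.074,
                            respiratory_disease = 0.159,
                            renal_failure = 0.013,
                            alcohol_drug_abuse = 0.039,
                            cardiovascular_disease = 0.024,
                            cancer = 0.037,
                            metastatic_cancer = 0.002,
                            diabetes = 0.035,
                            dyslipidemia = 0.112,
                            hbv_hcv = 0.078,
                            hypertension = 0.195),
                          taf_fraction = 1198 / 2658,
                          str_fraction_given_taf = 684 / 1198,
                          naive_fraction_given_taf = 478 / 1198,
                          pdc_target_distribution = default_pdc_mixture(),
                          persistence_prob = 0.785,
                          switch_prob = 0.18,
                          n_packages = 1L,
                          units_per_package = 30L,
                          cost_params = default_cost_params(),
                          hiv_hosp_rate_persistent = 0.08,
                          hiv_hosp_rate_nonpersistent = 0.20,
                          other_hosp_rate = 0.12,
                          outpatient_rate = 10,
                          other_drug_rate = 6,
                          death_prob = 0.015,
                          transfer_prob = 0.01,
                          study_start = as.Date("2014-01-01"),
                          study_end = as.Date("2020-12-31"),
                          inclusion_start = as.Date("2015-01-01"),
                          inclusion_end = as.Date("2019-12-31"),
                          seed = 1L) {
  probs <- c(male_fraction, taf_fraction, str_fraction_given_taf,
             naive_fraction_given_taf, persistence_prob, switch_prob,
             death_prob, transfer_prob, comorbidity_prevalences)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (persistence_prob + switch_prob > 1)
    stop("persistence_prob + switch_prob must not exceed 1", call. = FALSE)
  if (n_patients < 0 || n_patients != round(n_patients))
    stop("`n_patients` must be a non-negative integer", call. = FALSE)
  if (age_sd <= 0 || age_mean < 18)
    stop("age distribution must have sd > 0 and adult mean", call. = FALSE)
  unknown <- setdiff(names(comorbidity_prevalences),
                     names(default_comorbidity_map()))
  if (length(unknown))
    stop("unknown comorbidity in prevalences: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (nm in names(cost_params)) {
    p <- cost_params[[nm]]
    if (length(p) != 2 || any(p <= 0))
      stop("cost_params[['", nm, "']] must be positive c(shape, scale)",
           call. = FALSE)
  }
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  inclusion_start <- as.Date(inclusion_start)
  inclusion_end <- as.Date(inclusion_end)
  if (study_start >= study_end)
    stop("`study_start` must precede `study_end`", call. = FALSE)
  if (inclusion_start < study_start || inclusion_end > study_end)
    stop("inclusion window must lie inside the study window", call. = FALSE)
  if (as.integer(inclusion_start - study_start) < 365)
    stop("study data must start at least 365 days before the inclusion ",
         "window (characterization lookback)", call. = FALSE)
  if (as.integer(study_end - inclusion_end) < 365)
    stop("study data must extend at least 365 days past the inclusion ",
         "window (minimum follow-up)", call. = FALSE)
  rates <- c(hiv_hosp_rate_persistent, hiv_hosp_rate_nonpersistent,
             other_hosp_rate, outpatient_rate, other_drug_rate)
  if (any(rates < 0)) stop("event rates must be non-negative", call. = FALSE)
  structure(list(
    n_patients = as.integer(n_patients),
    male_fraction = male_fraction,
    age_mean = age_mean, age_sd = age_sd,
    comorbidity_prevalences = comorbidity_prevalences,
    taf_fraction = taf_fraction,
    str_fraction_given_taf = str_fraction_given_taf,
    naive_fraction_given_taf = naive_fraction_given_taf,
    pdc_target_distribution = pdc_target_distribution,
    persistence_prob = persistence_prob,
    switch_prob = switch_prob,
    n_packages = as.integer(n_packages),
    units_per_package = as.integer(units_per_package),
    cost_params = cost_params,
    hiv_hosp_rate_persistent = hiv_hosp_rate_persistent,
    hiv_hosp_rate_nonpersistent = hiv_hosp_rate_nonpersistent,
    other_hosp_rate = other_hosp_rate,
    outpatient_rate = outpatient_rate,
    other_drug_rate = other_drug_rate,
    death_prob = death_prob,
    transfer_prob = transfer_prob,
    study_start = study_start, study_end = study_end,
    inclusion_start = inclusion_start, inclusion_end = inclusion_end,
    seed = as.integer(seed)
  ), class = "claims_config")
}
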