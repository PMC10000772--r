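# Independent oracles and small fixture builders shared by the tests.

# Day-by-day boolean-calendar PDC: walk the window one day at a time,
# add each dispensation's supply to the stock on its day, consume one
# unit per covered day. Equivalent by construction to carry-forward
# stockpiling, computed without interval arithmetic.
oracle_pdc <- function(day, supply, window) {
  keep <- day >= 0 & day < window
  day <- day[keep]; supply <- supply[keep]
  add <- rep(0, window)
  for (i in seq_along(day)) add[day[i] + 1] <- add[day[i] + 1] + supply[i]
  stock <- 0; covered <- 0
  for (d in seq_len(window)) {
    stock <- stock + add[d]
    if (stock > 0) { covered <- covered + 1; stock <- stock - 1 }
  }
  100 * covered / window
}

# Direct numerical maximization of the gamma log-likelihood under an
# identity-link mean model (the shape parameter factors out of the
# score for the coefficients, so minimizing sum(log mu + y/mu) gives
# the MLE). Independent of the IRLS path.
oracle_gamma_identity <- function(y, X) {
  nll <- function(b) {
    mu <- drop(X %*% b)
    if (any(mu <= 0)) return(1e12)
    sum(log(mu) + y / mu)
  }
  gr <- function(b) {
    mu <- drop(X %*% b)
    if (any(mu <= 0)) return(rep(0, length(b)))
    drop(crossprod(X, (mu - y) / mu^2))
  }
  b <- c(mean(y), rep(0, ncol(X) - 1))
  b <- stats::optim(b, nll, gr, method = "BFGS",
                    control = list(maxit = 10000, reltol = 1e-14))$par
  # Newton polish with finite-difference Hessian for a tight optimum
  b <- stats::nlm(function(par) {
    v <- nll(par); attr(v, "gradient") <- gr(par); v
  }, b, gradtol = 1e-14, steptol = 1e-14, iterlim = 500)$estimate
  b
}

# Minimal linked tables for hand-built cohort scenarios. Every event
# table can be supplied as a tibble or left empty.
fixture_tables <- function(demographics, pharmacy = NULL, hospital = NULL,
                           outpatient = NULL) {
  empty <- artclaims::generate_cohort_tables(
    artclaims::claims_config(n_patients = 0))
  tabs <- empty[c("demographics", "pharmacy", "hospital", "outpatient")]
  tabs$demographics <- demographics
  if (!is.null(pharmacy)) tabs$pharmacy <- pharmacy
  if (!is.null(hospital)) tabs$hospital <- hospital
  if (!is.null(outpatient)) tabs$outpatient <- outpatient
  tabs
}

demo_row <- function(id = "A", birth = "1980-06-15", sex = "M",
                     death = NA, transfer = FALSE,
                     enroll_end = "2020-12-31") {
  tibble::tibble(patient_id = id, sex = sex,
                 birth_date = as.Date(birth),
                 enrollment_start = as.Date("2014-01-01"),
                 enrollment_end = as.Date(enroll_end),
                 death_date = as.Date(death),
                 transfer_out = transfer)
}

disp_rows <- function(id, atc, dates, packs = 1L, units = 30L,
                      cost = 600) {
  tibble::tibble(patient_id = id, atc_code = atc,
                 dispensation_date = as.Date(dates),
                 n_packages = as.integer(packs),
                 units_per_package = as.integer(units),
                 cost_eur = cost)
}

hosp_rows <- function(id, adm, icd9, drg = "127", tariff = 3000) {
  adm <- as.Date(adm)
  tibble::tibble(patient_id = id, admission_date = adm,
                 discharge_date = adm + 5L, icd9_codes = icd9,
                 drg_code = drg, tariff_eur = tariff)
}

outp_rows <- function(id, dates, type = "visit", tariff = 60) {
  tibble::tibble(patient_id = id, service_date = as.Date(dates),
                 service_type = type, tariff_eur = tariff)
}

# monthly dispensation dates: n refills every `by` days from `from`
monthly <- function(from, n, by = 30) as.Date(from) + by * (0:(n - 1))
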