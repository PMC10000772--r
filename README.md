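# artclaims

Drug utilization, adherence and cost analysis for antiretroviral
therapy (ART) in administrative claims, centered on tenofovir
alafenamide (TAF) based regimens.

Health systems that reimburse HIV care see patients only through
claims: pharmacy dispensations, hospital discharges, outpatient
tariffs. `artclaims` turns four such linked tables into the standard
pharmacoepidemiological quantities — who is on a TAF regimen and since
when, how completely they are covered by dispensed supply, whether
they persist, switch or discontinue, what they cost per year and which
cost item drives it — for analysts reproducing or extending
real-world drug-utilization studies of ART.

## What it computes

* **Cohort construction** — screening of adults with ART (ATC `J05A`)
  dispensations in 2015–2019; exclusion of single-dispensation
  patients, refill gaps over 12 months, and transfers; index at the
  first TAF dispensation; naive vs switcher from a half-open 365-day
  lookback; single-tablet (STR) vs multi-tablet (MTR) regimen from the
  index ATC; baseline comorbidity flags and a Charlson index modified
  to exclude the HIV item.
* **Adherence** — proportion of days covered with carry-forward
  stockpiling over a fixed 365-day window:
  `PDC = 100 x covered days / window days`, thresholds PDC > 95% and
  PDC > 85% (strict), strata <80 / 81–95 / >95.
* **Persistence** — classification from dispensing in the last
  quarter of follow-up year 1 (days 274–364 after index):
  persistent / switched / discontinued, a mutually exclusive and
  exhaustive partition, with persistence to any ART reported
  alongside persistence to TAF.
* **Costs** — per-patient annualized counts and costs for five items
  (ART drugs, other drugs, HIV hospitalizations DRG 488/489/490,
  other hospitalizations, outpatient services), kept in integer cents
  so items sum to totals exactly; single-pass mean + 3 SD outlier
  exclusion; stratification by persistence, adherence and inclusion
  year with Welch comparisons.
* **Cost model** — a gamma GLM with identity link for non-ART costs
  (effects in EUR) on adherence stratum, age class and Charlson
  score, fitted by IRLS with step-halving and verified against direct
  likelihood maximization.
* **Synthetic claims** — a seeded generator producing the four linked
  tables with known ground truth (regimen, target PDC, persistence
  label), so the whole pipeline is testable without any restricted
  data.

## Worked example

The numbered scripts under `analysis/` run the full study on a
synthetic population and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # four linked tables, 2658 patients
Rscript analysis/02_cohort.R     # screening, exclusions, characterization
Rscript analysis/03_utilization.R
Rscript analysis/04_costs.R
Rscript analysis/05_models.R
```

With the shipped seed, step 3 prints:

```
Drug utilization, overall and by subgroup (%):
    group    n pct_adherent_95 pct_adherent_85 pct_persistent pct_switched
  overall 1149            65.2            73.5           78.4         17.9
      MTR  479            68.1            76.2           80.8         16.9
      STR  670            63.1            71.6           76.7         18.7
    naive  451            65.0            74.3           79.8         16.9
 switcher  698            65.3            73.1           77.5         18.6

Persistence to any ART: 96.3% (vs 78.4% to the TAF regimen)
Status agreement with ground truth: 100.00%
```

78.4% of the 1149-patient TAF cohort is persistent (the generator's
truth is 78.5%), 17.9% switch regimen class and 3.7% discontinue; the
three shares sum to 100 because the classification is a partition.
Step 4 then reports first-year costs:

```
== first_year window: 1149 patients, 17 outliers above EUR 17867 ==
Mean annual total cost EUR 9759 (ART drugs 8181, other drugs 313,
  HIV hosp 373, other hosp 283, outpatient 609)
Persistent vs non-persistent total: EUR 10042 vs 8739 (p = 1.11e-11);
  HIV-hosp item: 303 vs 626 (p = 0.00396)
```

ART dispensing dominates total spend; non-persistent patients cost
about twice as much on the HIV-hospitalization item (their admission
rate is higher by construction) while costing less in total because
they stop filling ART. The methods vignette
(`vignettes/art-claims-methods.Rmd`) discusses why this last sign can
differ from observed cohorts. Step 5 fits the non-ART cost model and a
recovery simulation in which the fitter reproduces identity-scale
effects of EUR 1364, 2265 and 1736 within sampling error.

In code, the same pipeline is three calls:

```r
library(artclaims)
tabs  <- generate_cohort_tables(claims_config(n_patients = 1000, seed = 1))
built <- build_cohort(tabs)
util  <- compute_utilization(tabs, built$cohort)
costs <- exclude_outliers(tally_resources(tabs, built$cohort))
fit   <- fit_nonart_cost_model(costs$retained, built$cohort, util)
```

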