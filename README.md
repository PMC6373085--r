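# emrdq — data quality assessment for primary care EMR extracts

Electronic medical record (EMR) data extracted from primary health care
practices are increasingly reused for research, surveillance and quality
improvement, but their fitness for those purposes is never a given: problem
lists go unfilled, billing codes disagree with the clinical record, vitals are
recorded for some patients and not others, and what is recorded may be years
stale. `emrdq` implements a basic, reusable model for assessing the quality of
such an extract before it is used. It is aimed at researchers and data
custodians who receive a de-identified relational extract (patients, visits,
problem list, medications, labs, vitals, billing, immunizations, allergies)
and need a standard battery of quality measures, plus a synthetic EMR
generator so the whole pipeline can be exercised and validated without any
real patient data.

## The model

Eleven measure families in four domains, computed over the complete-case
cohort (patients with known sex and a computable index age at the window
start):

**Comparability** — is the practice population like the population at large?

* Age–sex structure versus a standard population: Pearson goodness-of-fit
  chi-square over 5-year-band × sex cells, `X² = Σ (O − E)² / E`, with
  expected counts from the standard's cell proportions (cells with expected
  counts under 5 pooled into adjacent bands); mean and median index age by
  sex.
* Crude and directly age-standardized prevalence of six test conditions
  (diabetes, hypertension, hypothyroidism, asthma, obesity, urinary tract
  infection): `p_std = Σ_s w_s p̂_s`, where `w_s` is the standard population's
  share of stratum `s` (5-year band × sex) and `p̂_s` the stratum prevalence;
  95% CIs use the gamma (Fay–Feuer) interval. Published prevalence figures
  are echoed alongside, never recomputed.

**Completeness** — how much of reality made it into the record?

* Sensitivity of billing codes against the rule-based case definitions as
  gold standard: `Se = |gold ∩ billed| / |gold|`.
* Consistency of capture: fraction of patients with ≥ 1 problem-list entry;
  with ≥ 1 allergy entry (an explicit "no known allergies" counts); and, among
  patients visiting in the final year, with ≥ 1 medication.
* Recording of blood pressure (18+, both components on one date), height and
  weight (all ages), with sex- and age-group chi-squares.
* Blood-pressure monitoring: fraction of diabetes patients, and of patients
  on a hypertension medication pattern (≥ 2 distinct oral anti-hypertensives
  or ≥ 1 diuretic), with a reading within 12 months of onset.

**Correctness** — is what was recorded right?

* Positive predictive value of billing codes: `PPV = |gold ∩ billed| /
  |billed|`.
* Unlikely age × procedure combinations: patients aged 10+ carrying a tetanus
  toxoid conjugate (DTaP-IPV-Hib-type) vaccination administered at age 10+.

**Currency** — is the record recent enough to represent the patient?

* Weight recorded within 1 year of the last visit for obese patients; a visit
  within 62 days after a positive pregnancy test; blood pressure, height and
  weight recorded no more than 1 year before the last visit.

Case definitions are declarative YAML (problem-list terms through a synonym
dictionary, medication classes with distinct-drug counts, lab thresholds,
paired BP readings, same-day BMI) — the shipped defaults are editable
starting points, not validated phenotyping algorithms. Zero-denominator
measures are flagged `undefined` (never 0% or 100%), measures whose source
tables are absent carry machine-readable `not computable` reasons, and
rendered counts between 0 and 5 are suppressed (`*`) while the JSON report
retains exact values.

## Worked example

Generate a synthetic practice of 2,500 patients and assess it:

```r
library(emrdq)
library(dplyr)

config <- synth_config(n_patients = 2500, seed = 42)
synth  <- synth_emr(config)
report <- run_assessment(synth$extract)
report
#> <dq_report> cohort n = 2484, window 2006-01-01 to 2010-12-31
#>   36 measures (0 undefined, 0 suppressed, 0 not computable)

tidy(report) |>
  filter(family %in% c("prevalence", "sensitivity")) |>
  select(family, condition_id, numerator, denominator, value_pct) |>
  mutate(value_pct = round_half_up(value_pct, 1))
#> # A tibble: 12 × 5
#>    family      condition_id            numerator denominator value_pct
#>    <chr>       <chr>                       <int>       <int>     <dbl>
#>  1 prevalence  diabetes                      199        2484       8
#>  2 prevalence  hypertension                  456        2484      18.4
#>  3 prevalence  hypothyroidism                155        2484       6.2
#>  4 prevalence  asthma                        109         535      20.4
#>  5 prevalence  obesity                       604        2484      24.3
#>  6 prevalence  urinary_tract_infection        66        2484       2.7
#>  7 sensitivity diabetes                      154         199      77.4
#>  8 sensitivity hypertension                  294         456      64.5
#>  9 sensitivity hypothyroidism                 81         155      52.3
#> 10 sensitivity asthma                         49         109      45
#> 11 sensitivity obesity                        84         604      13.9
#> 12 sensitivity urinary_tract_infection        39          66      59.1
```

Sixteen of 2,500 patients are dropped for missing sex or age (the exclusion
counts are on `attr(complete_case_cohort(synth$extract), "exclusions")`).
Crude prevalences sit near the generator's configured rates (e.g. diabetes
8.0% against a configured 6.8% at this roster size), and sensitivities near
the configured billing sensitivities — asthma is reported over the under-18
subcohort (535 patients) because its definition is age-restricted. The
ground-truth ledger in `synth$ground_truth` records every true condition,
onset and degradation flag, which is how the test suite checks that each
measure recovers its configured rate. `render_report(report, "report/")`
writes JSON, CSV and markdown renderings grouped by domain;
`autoplot(report)` draws the measures; `glance(report)` gives the one-row
summary.

For shell use, a thin CLI wraps the same functions:

```sh
Rscript inst/cli/emrdq.R synth  --out demo --n 2500 --seed 42
Rscript inst/cli/emrdq.R assess --extract demo --out report
```

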