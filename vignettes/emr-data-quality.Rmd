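---
title: "Assessing primary care EMR data quality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing primary care EMR data quality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emrdq)
```

## The assessment model

`emrdq` treats an EMR extract as a relational snapshot — a patient roster plus
dated record tables (visits, problem list, medications, laboratory results,
vitals, billing, immunizations, allergies) over a fixed observation window —
and asks four questions of it, one per domain:

* **Comparability.** Does the practice population resemble an external
  standard, in age–sex structure and in the prevalence of common conditions?
  If not, findings from these data generalize poorly.
* **Completeness.** What fraction of the observations one would expect to
  exist were actually recorded — cases captured by billing, key record types
  present, vitals measured?
* **Correctness.** Of what was recorded, how much is right — do billing codes
  predict true cases, and do implausible age-procedure combinations appear?
* **Currency.** Is the record recent enough to describe the patient now —
  vitals within a year of the last visit, follow-up soon after a positive
  pregnancy test?

All measures are computed on the *complete-case cohort*: patients with
non-missing sex and a computable, non-negative index age at the index date
(by default the window start, matching the "as of" convention used when
extracts are described). Exclusions are counted by reason, and cohort size
plus exclusions always equals the roster size. Index age is completed years
(floored). Birth date is the stored primitive; extracts that supply only an
integer age receive a synthetic July 1 birth date with an `age_derived`
provenance flag, so both index age and age-at-event remain derivable.

A deliberate invariant runs through every measure: **degenerate inputs are
loud**. A zero denominator yields an `undefined` flag, never 0% or 100%; an
absent source table yields a `not computable` row with a machine-readable
reason; a definition that loses clauses to absent tables is marked degraded.
A report therefore always contains all eleven measure families, computed or
explained.

## Case definitions

Each of the six test conditions (diabetes, hypertension, hypothyroidism,
asthma, obesity, urinary tract infection) is identified by a declarative
definition: a *disjunction of clauses*, where a clause is a problem-list term
set, a medication rule, a laboratory threshold, a paired blood-pressure rule,
a same-day BMI rule, or a lab-plus-medication rule. The shipped defaults
(`default_case_definitions()`, YAML at
`system.file("extdata", "default_definitions.yaml", package = "emrdq")`) are
assembled from the data elements such definitions typically use — problem
list, medications, labs, blood pressure, BMI — and are explicitly editable
configuration: thresholds (HbA1c ≥ 6.5%, fasting glucose ≥ 7.0 mmol/L,
BP ≥ 140/90 on ≥ 2 distinct dates, BMI ≥ 30) and term/medication lists all
live in the YAML, not in code. Two defaults deserve flags:

* Whether a hypertension or diabetes definition should include BP/lab
  thresholds at all, and whether "2 or more oral anti-hypertensives" means
  distinct drugs or prescription events, are genuinely open choices; we ship
  thresholds included and count *distinct drug names*.
* The obesity default accepts either a same-day height + weight pair giving
  BMI ≥ 30 **or** an obesity problem-list term. Problem lists do record
  obesity, and a term clause keeps the definition usable in extracts whose
  vitals are sparse; the BMI clause remains the primary route. Same-day
  pairing is the strict default because height changes slowly but pairing
  across years is a stronger assumption.

Free text is handled by lexical normalization only (lowercase, punctuation
and whitespace collapsed) followed by a synonym dictionary that maps variants
("DM2", "Type II Diabetes Mellitus") to one token. There is no NLP: unmatched
text simply matches nothing.

**Onset dates.** The onset of a condition is the earliest date at which any
clause *first becomes satisfied*. For single-record atoms that is the earliest
qualifying record. For count-based atoms (k distinct drugs, 2 high BP dates)
we take the date of the k-th distinct qualifying item — the day the rule's
evidence became sufficient — rather than the first item's date, which would
date a two-drug rule before the rule holds. For the lab-plus-medication rule
the onset is the medication date of the earliest qualifying pair.

## Statistical choices

* **Chi-square versus a standard population.** Expected counts are the
  standard's cell proportions times the observed total, so the statistic is
  invariant to the standard's absolute size. Cells with expected counts below
  5 (the conventional validity rule) are pooled into adjacent age bands
  within sex, and the pooled-cell count is reported; degrees of freedom are
  cells-after-pooling minus one. Stratified recording tests are Pearson
  independence chi-squares without continuity correction; degenerate tables
  (a single stratum, or an all-recorded margin) return `NA` statistics rather
  than failing.
* **Direct standardization.** Strata are 5-year age band × sex by default
  (`by_sex = FALSE` gives age-only strata; both are offered because either
  convention is defensible). Strata with no cohort members are dropped and
  the remaining standard weights renormalized, with the count of empty strata
  reported. The 95% CI is the gamma (Fay–Feuer) interval, standard practice
  for directly standardized rates; its lower bound is exactly 0 when there
  are no cases. Conditions whose definition is age-restricted (asthma,
  under 18) are reported *crude-only over the restricted subcohort* —
  standardizing a rate that is structurally zero outside the restriction
  would be misleading, and the restricted denominator is the one the
  configured prevalence refers to.
* **Windows.** "Within 12 months" and "within 1 year" are closed 365-day
  windows; monitoring follows onset (`[onset, onset + 365]`), timeliness
  precedes the last visit (`[last_visit − 365, last_visit]`). "Within two
  months" after a positive pregnancy test is a fixed 62-day window,
  `(result, result + 62]` — calendar-month arithmetic is ambiguous across
  month lengths, and a visit on the result day itself is the test visit, not
  follow-up. All window lengths are `dq_config()` parameters (days).
* **Blood pressure.** A BP "recording" requires systolic and diastolic on the
  same date; a lenient mode accepting single components exists but is off by
  default. BP denominators are patients aged 18+ at index.
* **Rounding and rendering.** Percentages render half-up to one decimal
  (47.158% → "47.2"); p-values below 0.001 render as "<0.001". Small-cell
  suppression (rendered counts strictly between 0 and 5 become "*") is
  render-only: the report object and its JSON rendering keep exact counts
  behind the `suppressed` flag, so downstream computation is unaffected, and
  an exact zero renders as 0.0 rather than being suppressed.
* **Determinism.** Identical extract + configuration give byte-identical
  reports; the configuration hash is embedded in the report metadata.

## The synthetic EMR generator

The generator (`synth_config()`, `synth_emr()`) stands in for real practice
extracts, which cannot be shared. It emulates exactly the statistical
structure the measures consume:

* a roster drawn from a standard population's age–sex cells, with uniform
  ages within bands and configurable missing-sex/missing-age rates;
* per-condition true case status (configured prevalence; asthma only under
  18), with onset dates uniform over the window's first half so 12-month
  follow-up windows fit inside the window;
* billing as **two coin flips** — a case is billed with the configured
  sensitivity, a non-case with a false-billing rate — giving analytically
  known expected sensitivity and PPV;
* record-type presence at configured recording rates, with content consistent
  with case status (hypertensive patients' readings are high, non-obese
  same-day pairs imply BMI < 30, non-diabetic glucose stays below threshold),
  and a free-text dialect that emits randomized-case/punctuation synonyms;
* timeliness flags that place vitals inside `[last_visit − 365, last_visit]`
  with the configured probability and otherwise in the preceding year, and
  follow-up flags that place a BP reading inside the onset window (or a
  visit inside the pregnancy window) with the configured probability.

One calibration detail matters for validation. A patient whose case status
requires a record type to be discoverable (a problem-list entry for any case,
a BP reading for patients needing monitoring, a weight for obese patients)
always carries it; the remaining patients' presence probability is then
adjusted so the *marginal* rate equals the knob exactly:
`q = (p·N − m) / (N − m)` for `m` forced patients. This keeps two properties
simultaneously — the pipeline recovers the ground-truth ledger exactly when
no degradation is applied, and every recording measure is an unbiased
estimate of its knob — which would otherwise conflict. Configurations with
`p·N < m` are infeasible and produce a warning with the attainable minimum.

Defaults describe a mid-sized practice network: 2,500 patients over a
2006–2010 window (the roster size keeps examples fast; validation uses
10,000), prevalences at published population figures for the six conditions
(6.8, 19.1, 7.1, 21.1 among under-18s, 24.1, and 3.0% for UTI, an acute
condition with no published population prevalence), billing sensitivities and
recording/timeliness rates in the mid-range reported for EMR-derived
datasets, 90% monitoring follow-up, 50% pregnancy follow-up, and a zero
tetanus-misrecording rate. Expected fractions under these defaults: a
vitals-timeliness measure estimates `recording × timeliness` (presence and
recency are independent coins), while the obesity weight-timeliness measure
estimates the timeliness fraction alone (every obese patient carries a
weight record).

What the generator does **not** emulate — and therefore what passing tests do
not show about real data: longitudinal disease progression, visit patterns
correlated with illness, age- or sex-dependent recording behaviour,
inter-practice heterogeneity, coding idiosyncrasies beyond the two dialects,
and measurement error in vitals. Recovery of a knob on synthetic data
validates the *measurement machinery*, not any claim about real extracts.

`degrade_emr()` applies quality-reducing knobs only (row deletion by table,
backdating vitals); every completeness and currency measure is non-increasing
under them, which the test suite asserts, along with exact annihilation
(deleting all vitals drives the six vitals measures to 0%).

## Validation strategy and problem sizes

The test suite validates three ways, at sizes chosen to keep the default run
inside a few minutes:

1. **Worked examples and closed forms** on hand-built fixtures: printed
   roster percentages, the two-cell chi-square (statistic 4.0, df 1), the
   two-stratum standardization (17.0%), window edges (+365/+366, +62/+63
   days), BMI 80 kg / 1.60 m → 31.25.
2. **Oracle equivalence** on ≤ 200-patient fixtures: every measure against an
   independent brute-force implementation (plain loops, set arithmetic,
   textbook Σ(O−E)²/E) to 1e-12 relative tolerance, and the vectorized case
   engine against both a per-patient evaluation and a loop oracle.
3. **Parameter recovery** on 10,000-patient extracts across 20 seeds: each
   configured rate (prevalence, billing sensitivity and PPV via the two-coin
   model, six recording rates, all timeliness and follow-up fractions) must
   fall within 3 binomial standard errors of its expectation in at least
   19 of 20 seeds — the 3-SE band itself admits roughly one excursion in
   370 draws, so a single stray seed is within the criterion's tolerance.

## Known limitations

* Term matching is exact after normalization; misspellings and local jargon
  need dictionary entries.
* The timeliness denominator excludes patients with no visits (no anchor
  exists); in extracts where such patients are common, the nesting relation
  "timeliness ≤ recording" can fail on denominators even though numerators
  always nest.
* Sensitivity and PPV treat the case definitions as gold standard; they
  measure concordance with billing, not clinical truth, and no
  specificity/NPV is computed because no true-negative standard exists in
  these data.
* The bundled standard population is a synthetic census-like structure for
  examples and tests; real assessments should supply an actual census table
  via `read_standard_population()`.
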