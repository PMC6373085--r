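# Default age grouping for stratified chi-squares; configurable everywhere.
default_age_breaks <- c(0, 18, 45, 60)

#' Group ages for stratified tests
#'
#' @param age Integer ages.
#' @param breaks Lower bounds of the groups (default `c(0, 18, 45, 60)` giving
#'   0-17, 18-44, 45-59, 60+).
#' @return Ordered factor of group labels.
#' @export
age_group <- function(age, breaks = default_age_breaks) {
  breaks <- as.integer(sort(unique(breaks)))
  k <- length(breaks)
  labels <- c(if (k > 1) sprintf("%d-%d", breaks[-k], breaks[-1] - 1L),
              sprintf("%d+", breaks[k]))
  idx <- findInterval(age, breaks)
  idx[idx == 0] <- 1L
  factor(labels[idx], levels = labels, ordered = TRUE)
}

# Pearson chi-square of independence (no continuity correction) between a
# stratum factor and a recorded flag; NA when degenerate.
strat_chisq <- function(stratum, recorded) {
  tab <- table(factor(stratum), factor(recorded, levels = c(FALSE, TRUE)))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2 || any(colSums(tab) == 0)) {
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_))
  }
  test <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(test$statistic),
       df = as.integer(unname(test$parameter)),
       p_value = unname(test$p.value))
}

measure_row <- function(domain, measure, condition_id = NA_character_,
                        numerator = NA_integer_, denominator = NA_integer_,
                        ...) {
  und <- !is.na(denominator) && denominator == 0
  tibble(
    domain = domain, measure = measure, condition_id = condition_id,
    numerator = as.integer(numerator), denominator = as.integer(denominator),
    value_pct = if (und || is.na(denominator)) NA_real_ else
      100 * numerator / denominator,
    undefined = und,
    ...
  )
}

concordance <- function(kind, gold_ids, billing_ids, condition_id) {
  overlap <- length(intersect(gold_ids, billing_ids))
  denom <- if (kind == "sensitivity") length(gold_ids) else length(billing_ids)
  measure_row(
    domain = if (kind == "sensitivity") "completeness" else "correctness",
    measure = kind, condition_id = condition_id,
    numerator = overlap, denominator = denom,
    n_gold = length(gold_ids), n_billing = length(billing_ids),
    n_overlap = overlap
  )
}

case_ids <- function(cases) cases$patient_id[cases$is_case]

#' Sensitivity of billing codes against the case-definition gold standard
#'
#' `100 * |gold AND billing| / |gold|`, the fraction of definition-identified
#' cases that also carry a billing code. Undefined (flagged, not 0) when there
#' are no gold-standard cases.
#'
#' @param gold A `case_set` from [identify_cases()] (the gold standard).
#' @param billing Character vector of billed patient ids
#'   ([billing_positives()]), restricted to the same cohort.
#' @return One-row measure tibble with `n_gold`, `n_billing`, `n_overlap`,
#'   `value_pct`, `undefined`.
#' @export
sensitivity_vs_billing <- function(gold, billing) {
  concordance("sensitivity", case_ids(gold), unique(billing),
              attr(gold, "condition_id") %||% NA_character_)
}

#' Positive predictive value of billing codes
#'
#' `100 * |gold AND billing| / |billing|`; undefined when no patient is
#' billed. Together with [sensitivity_vs_billing()] it satisfies the identity
#' `sensitivity * n_gold == ppv * n_billing == n_overlap` (in counts).
#'
#' @inheritParams sensitivity_vs_billing
#' @return One-row measure tibble.
#' @export
ppv_vs_billing <- function(gold, billing) {
  concordance("ppv", case_ids(gold), unique(billing),
              attr(gold, "condition_id") %||% NA_character_)
}

#' Consistency of capture
#'
#' Three completeness proportions: patients with at least one problem-list
#' entry; patients with at least one allergy entry (an explicit
#' "no known allergies" marker counts); and, among patients with a visit in
#' the final year of the window, those with at least one prescribed
#' medication.
#'
#' @param extract An [emr_extract()].
#' @param cohort A [complete_case_cohort()].
#' @param final_year_days Length of the "last year of the database" window in
#'   days (default 365; the window is `[window_end - 365, window_end]`).
#' @return Three-row measure tibble (`problem_list`, `allergy_record`,
#'   `medications`).
#' @export
consistency_of_capture <- function(extract, cohort, final_year_days = 365) {
  ids <- cohort$patient_id
  has_rows <- function(tb) ids %in% (if (is.null(tb)) character() else tb$patient_id)

  problem <- measure_row("completeness", "problem_list",
                         numerator = sum(has_rows(extract$problems)),
                         denominator = length(ids))
  allergy <- measure_row("completeness", "allergy_record",
                         numerator = sum(has_rows(extract$allergies)),
                         denominator = length(ids))

  v <- extract$visits
  recent <- if (is.null(v)) character() else unique(
    v$patient_id[v$visit_date >= extract$window_end - final_year_days])
  recent <- intersect(ids, recent)
  meds <- extract$medications
  med_ids <- if (is.null(meds)) character() else unique(meds$patient_id)
  medication <- measure_row("completeness", "medications",
                            numerator = length(intersect(recent, med_ids)),
                            denominator = length(recent))
  bind_rows(problem, allergy, medication)
}

# Patient-date pairs at which a vitals kind is considered recorded. A blood
# pressure recording requires both components on one date (strict default).
vitals_record_dates <- function(extract, kind, lenient_bp = FALSE) {
  if (kind == "bp") {
    if (lenient_bp) {
      v <- extract$vitals
      if (is.null(v)) return(tibble(patient_id = character(),
                                    date = as.Date(character())))
      v |>
        filter(.data$kind %in% c("systolic_bp", "diastolic_bp")) |>
        distinct(.data$patient_id, date = .data$measure_date)
    } else {
      bp_readings(extract) |> select("patient_id", "date")
    }
  } else {
    v <- extract$vitals
    if (is.null(v)) return(tibble(patient_id = character(),
                                  date = as.Date(character())))
    v[v$kind == kind, ] |>
      distinct(.data$patient_id, date = .data$measure_date)
  }
}

vitals_denominator <- function(cohort, kind, bp_min_age = 18) {
  if (kind == "bp") cohort[cohort$index_age >= bp_min_age, ] else cohort
}

vitals_measure <- function(extract, cohort, kind, domain, measure,
                           dates_filter = NULL, age_breaks = default_age_breaks,
                           lenient_bp = FALSE, bp_min_age = 18) {
  stopifnot(kind %in% c("bp", "height", "weight"))
  denom <- vitals_denominator(cohort, kind, bp_min_age)
  rec_dates <- vitals_record_dates(extract, kind, lenient_bp)
  n_excluded <- 0L
  if (!is.null(dates_filter)) {
    anchors <- last_visit_dates(extract)
    denom0 <- nrow(denom)
    denom <- denom |> inner_join(anchors, by = "patient_id")
    n_excluded <- denom0 - nrow(denom)
    rec_dates <- rec_dates |>
      inner_join(select(denom, "patient_id", "last_visit"), by = "patient_id") |>
      filter(dates_filter(.data$date, .data$last_visit))
  }
  recorded <- denom$patient_id %in% rec_dates$patient_id

  sex_test <- strat_chisq(denom$sex, recorded)
  age_test <- strat_chisq(age_group(denom$index_age, age_breaks), recorded)

  row <- measure_row(domain, measure, condition_id = kind,
                     numerator = sum(recorded), denominator = nrow(denom),
                     stat_sex = sex_test$statistic, df_sex = sex_test$df,
                     p_sex = sex_test$p_value,
                     stat_age = age_test$statistic, df_age = age_test$df,
                     p_age = age_test$p_value)
  if (!is.null(dates_filter)) row$n_excluded_no_visit <- n_excluded
  row
}

#' Recording of blood pressure, height and weight
#'
#' Proportion of patients with at least one recording of the given kind:
#' blood pressure among patients aged 18 and over (a recording needs both
#' systolic and diastolic on one date unless `lenient_bp`), height and weight
#' among all ages. Sex-by-recorded and age-group-by-recorded chi-squares
#' (no continuity correction) accompany the proportion.
#'
#' @param extract An [emr_extract()].
#' @param cohort A [complete_case_cohort()].
#' @param kind `"bp"`, `"height"` or `"weight"`.
#' @param age_breaks Age-group lower bounds for the stratified test.
#' @param lenient_bp Count single-component blood-pressure rows (default off).
#' @param bp_min_age Minimum index age for the blood-pressure denominator.
#' @return One-row measure tibble with test columns `stat_sex`, `p_sex`,
#'   `stat_age`, `p_age`.
#' @export
vitals_recording <- function(extract, cohort, kind,
                             age_breaks = default_age_breaks,
                             lenient_bp = FALSE, bp_min_age = 18) {
  vitals_measure(extract, cohort, kind, "completeness",
                 paste0("recording_", kind), dates_filter = NULL,
                 age_breaks = age_breaks, lenient_bp = lenient_bp,
                 bp_min_age = bp_min_age)
}

#' Blood-pressure recording among patients requiring monitoring
#'
#' For two groups — patients with diabetes, and patients on a hypertension
#' medication pattern — the fraction with at least one blood-pressure
#' recording within `window_days` days after their onset date (closed window
#' `[onset, onset + window_days]`).
#'
#' @param extract An [emr_extract()].
#' @param diabetes_cases A `case_set` for diabetes (onset dates required).
#' @param hypertension_med Tibble `patient_id`, `onset_date` for the
#'   hypertension-medication group (see
#'   [hypertension_medication_patients()]; pass the hypertension case onset
#'   when available).
#' @param window_days Monitoring window length (default 365).
#' @param lenient_bp See [vitals_recording()].
#' @return Two-row measure tibble (groups `diabetes`, `hypertension_meds`).
#' @export
bp_among_requiring <- function(extract, diabetes_cases, hypertension_med,
                               window_days = 365, lenient_bp = FALSE) {
  bp <- vitals_record_dates(extract, "bp", lenient_bp)
  group_rate <- function(onsets, label, condition) {
    if (nrow(onsets) > 0 && any(is.na(onsets$onset_date))) {
      abort("Every member of a monitoring group must have an onset date.")
    }
    hit <- onsets |>
      inner_join(bp, by = "patient_id", relationship = "one-to-many") |>
      filter(.data$date >= .data$onset_date,
             .data$date <= .data$onset_date + window_days) |>
      distinct(.data$patient_id)
    measure_row("completeness", label, condition_id = condition,
                numerator = nrow(hit), denominator = nrow(onsets))
  }
  diab <- tibble(patient_id = case_ids(diabetes_cases),
                 onset_date = diabetes_cases$onset_date[diabetes_cases$is_case])
  ht <- hypertension_med
  if ("pattern_date" %in% names(ht) && !"onset_date" %in% names(ht)) {
    ht <- rename(ht, onset_date = "pattern_date")
  }
  bind_rows(
    group_rate(diab, "bp_after_diabetes_onset", "diabetes"),
    group_rate(ht, "bp_after_hypertension_onset", "hypertension_meds")
  )
}
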