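#' Unlikely age-procedure combinations: tetanus conjugate vaccination at 10+
#'
#' The fraction of patients aged `min_age` or more (at the window end) with a
#' tetanus toxoid conjugate vaccine (DTaP-IPV-Hib style, usually reserved for
#' children under 10) administered at age `min_age` or more — age is taken at
#' the administration date, not at assessment.
#'
#' @param extract An [emr_extract()].
#' @param cohort A [complete_case_cohort()].
#' @param vaccine_terms Normalized fragments identifying the vaccine among
#'   immunization entries.
#' @param min_age Age threshold in years (default 10).
#' @return One-row measure tibble (domain `correctness`).
#' @export
unlikely_vaccination <- function(extract, cohort,
                                 vaccine_terms = c("dtap", "tetanus", "dpt"),
                                 min_age = 10) {
  eligible <- cohort[years_between(cohort$birth_date, extract$window_end) >=
                       min_age, ]
  imm <- extract$immunizations
  flagged <- character()
  if (!is.null(imm) && nrow(imm) > 0) {
    norm <- normalize_text(imm$vaccine)
    hit <- Reduce(`|`, lapply(vaccine_terms, function(t)
      stringr::str_detect(norm, stringr::fixed(normalize_text(t)))))
    rows <- imm[hit, ] |>
      inner_join(select(eligible, "patient_id", "birth_date"),
                 by = "patient_id") |>
      filter(years_between(.data$birth_date, .data$given_date) >= min_age)
    flagged <- unique(rows$patient_id)
  }
  measure_row("correctness", "unlikely_vaccination",
              numerator = length(flagged), denominator = nrow(eligible))
}

#' Timeliness of weight recording for patients with obesity
#'
#' Fraction of obese patients (by the case definition) with at least one
#' weight recording within `window_days` days before their last visit
#' (closed window `[last_visit - window_days, last_visit]`). Obese patients
#' with no visits have no anchor and are excluded from the denominator; the
#' excluded count is reported.
#'
#' @param extract An [emr_extract()].
#' @param obesity_cases A `case_set` for obesity.
#' @param window_days Window length (default 365).
#' @return One-row measure tibble (domain `currency`) with
#'   `n_excluded_no_visit`.
#' @export
weight_timeliness_obesity <- function(extract, obesity_cases,
                                      window_days = 365) {
  obese <- tibble(patient_id = case_ids(obesity_cases))
  anchors <- last_visit_dates(extract)
  denom <- obese |> inner_join(anchors, by = "patient_id")
  wt <- vitals_record_dates(extract, "weight")
  hit <- denom |>
    inner_join(wt, by = "patient_id", relationship = "one-to-many") |>
    filter(.data$date >= .data$last_visit - window_days,
           .data$date <= .data$last_visit) |>
    distinct(.data$patient_id)
  measure_row("currency", "weight_timeliness_obesity",
              condition_id = "obesity",
              numerator = nrow(hit), denominator = nrow(denom),
              n_excluded_no_visit = nrow(obese) - nrow(denom))
}

#' Timeliness of the visit after a positive pregnancy test
#'
#' Among cohort patients with at least one positive pregnancy laboratory
#' result, the fraction with at least one visit within `window_days` days
#' after a positive result (window `(result, result + window_days]`; a
#' patient counts if any of their positive results has a qualifying visit).
#'
#' @param extract An [emr_extract()].
#' @param cohort A [complete_case_cohort()].
#' @param test_code Laboratory test code of the pregnancy test.
#' @param window_days "Two months" as a fixed day window (default 62 days).
#' @return One-row measure tibble (domain `currency`).
#' @export
pregnancy_followup <- function(extract, cohort, test_code = "pregnancy_hcg",
                               window_days = 62) {
  pos <- sat_labs_all_dates(extract, test_code, "positive") |>
    filter(.data$patient_id %in% cohort$patient_id)
  denom_ids <- unique(pos$patient_id)
  v <- extract$visits
  hits <- character()
  if (!is.null(v) && length(denom_ids) > 0) {
    hits <- pos |>
      inner_join(select(v, "patient_id", "visit_date"), by = "patient_id",
                 relationship = "many-to-many") |>
      filter(.data$visit_date > .data$result_date,
             .data$visit_date <= .data$result_date + window_days) |>
      distinct(.data$patient_id) |>
      dplyr::pull("patient_id")
  }
  measure_row("currency", "pregnancy_followup",
              numerator = length(hits), denominator = length(denom_ids))
}

#' Timeliness of blood pressure, height and weight recording
#'
#' Fraction of patients with at least one recording of the kind no more than
#' `window_days` days before their last visit (window
#' `[last_visit - window_days, last_visit]`). Denominators mirror
#' [vitals_recording()] (blood pressure: 18+), additionally requiring at
#' least one visit to anchor the window (excluded counts reported); the same
#' sex and age-group chi-squares are attached.
#'
#' @inheritParams vitals_recording
#' @param window_days Window length (default 365).
#' @return One-row measure tibble (domain `currency`).
#' @export
vitals_timeliness <- function(extract, cohort, kind, window_days = 365,
                              age_breaks = default_age_breaks,
                              lenient_bp = FALSE, bp_min_age = 18) {
  vitals_measure(
    extract, cohort, kind, "currency", paste0("timeliness_", kind),
    dates_filter = function(date, last_visit)
      date >= last_visit - window_days & date <= last_visit,
    age_breaks = age_breaks, lenient_bp = lenient_bp, bp_min_age = bp_min_age)
}
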