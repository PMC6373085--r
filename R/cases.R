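# Clause evaluation machinery. Each helper returns a tibble
# (patient_id, sat_date): the patients satisfying the clause and the date on
# which it first became satisfied.

empty_sat <- function() {
  tibble(patient_id = character(), sat_date = as.Date(character()))
}

# Earliest date per patient; empty-safe (dplyr would warn on min() over an
# empty frame while inferring the output type).
min_date_by_patient <- function(df, date_col) {
  if (nrow(df) == 0) return(empty_sat())
  df |>
    group_by(.data$patient_id) |>
    summarise(sat_date = min(.data[[date_col]]), .groups = "drop")
}

# Date on which the k-th distinct qualifying item first appears.
kth_distinct_date <- function(df, key_col, k) {
  if (nrow(df) == 0) return(empty_sat())
  df |>
    group_by(.data$patient_id, key = .data[[key_col]]) |>
    summarise(first_date = min(.data$date), .groups = "drop_last") |>
    summarise(
      sat_date = if (dplyr::n() >= k) sort(.data$first_date)[k] else as.Date(NA),
      .groups = "drop"
    ) |>
    filter(!is.na(.data$sat_date))
}

sat_problem_terms <- function(extract, terms, dictionary) {
  pr <- extract$problems
  if (is.null(pr) || nrow(pr) == 0) return(empty_sat())
  tok <- normalize_term(pr$text, dictionary)
  hit <- tok %in% terms
  if (!all(is.na(pr$code))) {
    hit <- hit | (!is.na(pr$code) & normalize_text(pr$code) %in% terms)
  }
  min_date_by_patient(pr[hit, ], "entry_date")
}

# Matched canonical drug label, or NA when the row matches neither class nor name.
match_medication <- function(meds, atom) {
  label <- rep(NA_character_, nrow(meds))
  for (nm in atom$names %||% character()) {
    miss <- is.na(label)
    hit <- miss & stringr::str_detect(normalize_text(meds$name),
                                      stringr::fixed(normalize_text(nm)))
    label[hit] <- normalize_text(nm)
  }
  if (!is.null(atom$classes) && "class_code" %in% names(meds)) {
    for (cl in atom$classes) {
      miss <- is.na(label)
      hit <- miss & !is.na(meds$class_code) &
        startsWith(meds$class_code, cl)
      label[hit] <- normalize_text(meds$name[hit])
    }
  }
  label
}

sat_medication <- function(extract, atom) {
  meds <- extract$medications
  if (is.null(meds) || nrow(meds) == 0) return(empty_sat())
  label <- match_medication(meds, atom)
  k <- atom$min_distinct %||% 1
  matched <- meds[!is.na(label), ]
  if (nrow(matched) == 0) return(empty_sat())
  matched$drug <- label[!is.na(label)]
  matched |>
    transmute(.data$patient_id, .data$drug, date = .data$start_date) |>
    kth_distinct_date("drug", k)
}

sat_lab <- function(extract, atom) {
  labs <- extract$labs
  if (is.null(labs) || nrow(labs) == 0) return(empty_sat())
  rows <- labs[normalize_text(labs$test_code) == normalize_text(atom$test), ]
  if (nrow(rows) == 0) return(empty_sat())
  if (!is.null(atom$qualitative)) {
    rows <- rows[!is.na(rows$qualitative) &
                   rows$qualitative == atom$qualitative, ]
  } else {
    if (!is.null(atom$units)) {
      bad <- !is.na(rows$units) &
        normalize_text(rows$units) != normalize_text(atom$units)
      if (any(bad)) {
        abort(sprintf(
          "Unit mismatch for lab `%s`: definition expects %s, extract has %s.",
          atom$test, atom$units,
          paste(unique(rows$units[bad]), collapse = ", ")))
      }
    }
    cmp <- switch(atom$op,
                  ">=" = `>=`, ">" = `>`, "<=" = `<=`, "<" = `<`, "==" = `==`)
    rows <- rows[!is.na(rows$value) & cmp(rows$value, atom$threshold), ]
  }
  min_date_by_patient(rows, "result_date")
}

# Paired same-day systolic/diastolic readings, one row per patient-date.
bp_readings <- function(extract) {
  v <- extract$vitals
  if (is.null(v) || nrow(v) == 0) {
    return(tibble(patient_id = character(), date = as.Date(character()),
                  systolic = numeric(), diastolic = numeric()))
  }
  v <- filter(v, .data$kind %in% c("systolic_bp", "diastolic_bp"))
  if (nrow(v) == 0) {
    return(tibble(patient_id = character(), date = as.Date(character()),
                  systolic = numeric(), diastolic = numeric()))
  }
  v |>
    group_by(.data$patient_id, date = .data$measure_date, .data$kind) |>
    summarise(value = max(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "value") |>
    (\(d) {
      for (col in c("systolic_bp", "diastolic_bp")) {
        if (!col %in% names(d)) d[[col]] <- NA_real_
      }
      d
    })() |>
    filter(!is.na(.data$systolic_bp), !is.na(.data$diastolic_bp)) |>
    rename(systolic = "systolic_bp", diastolic = "diastolic_bp")
}

sat_bp <- function(extract, atom) {
  readings <- bp_readings(extract)
  if (nrow(readings) == 0) return(empty_sat())
  high <- readings |>
    filter(.data$systolic >= atom$systolic | .data$diastolic >= atom$diastolic)
  k <- atom$min_count %||% 2
  high$day <- high$date
  kth_distinct_date(high, "day", k)
}

height_m <- function(value, units) {
  dplyr::case_when(
    !is.na(units) & normalize_text(units) == "cm" ~ value / 100,
    !is.na(units) & normalize_text(units) == "m" ~ value,
    is.na(units) & value > 3 ~ value / 100, # bare centimetre readings
    TRUE ~ value
  )
}

weight_kg <- function(value, units) {
  dplyr::case_when(
    !is.na(units) & normalize_text(units) %in% c("lb", "lbs") ~ value * 0.45359237,
    TRUE ~ value
  )
}

# Same-day height + weight pairs with derived BMI (kg/m^2).
bmi_pairs <- function(extract) {
  v <- extract$vitals
  if (is.null(v) || nrow(v) == 0) {
    return(tibble(patient_id = character(), date = as.Date(character()),
                  bmi = numeric()))
  }
  hw <- v |>
    filter(.data$kind %in% c("height", "weight")) |>
    group_by(.data$patient_id, date = .data$measure_date, .data$kind) |>
    summarise(value = dplyr::first(.data$value),
              units = dplyr::first(.data$units), .groups = "drop")
  h <- hw |> filter(.data$kind == "height") |>
    transmute(.data$patient_id, .data$date,
              h_m = height_m(.data$value, .data$units))
  w <- hw |> filter(.data$kind == "weight") |>
    transmute(.data$patient_id, .data$date,
              w_kg = weight_kg(.data$value, .data$units))
  inner_join(h, w, by = c("patient_id", "date")) |>
    mutate(bmi = .data$w_kg / .data$h_m^2) |>
    select("patient_id", "date", "bmi")
}

sat_bmi <- function(extract, atom) {
  pairs <- bmi_pairs(extract)
  min_date_by_patient(filter(pairs, .data$bmi >= atom$threshold), "date")
}

sat_lab_med <- function(extract, atom) {
  pos <- sat_labs_all_dates(extract, atom$test, atom$qualitative %||% "positive")
  if (nrow(pos) == 0) return(empty_sat())
  meds <- extract$medications
  if (is.null(meds) || nrow(meds) == 0) return(empty_sat())
  label <- match_medication(
    meds, list(classes = atom$med_classes, names = atom$med_names))
  matched <- meds[!is.na(label), c("patient_id", "start_date")]
  if (nrow(matched) == 0) return(empty_sat())
  within <- atom$within_days %||% 14
  qualifying <- inner_join(pos, matched, by = "patient_id",
                           relationship = "many-to-many") |>
    filter(.data$start_date >= .data$result_date,
           .data$start_date <= .data$result_date + within)
  min_date_by_patient(qualifying, "start_date")
}

# All dates of a qualitative lab result (used by lab_med and pregnancy).
sat_labs_all_dates <- function(extract, test, qualitative) {
  labs <- extract$labs
  if (is.null(labs) || nrow(labs) == 0) {
    return(tibble(patient_id = character(), result_date = as.Date(character())))
  }
  wanted <- qualitative
  labs |>
    filter(normalize_text(.data$test_code) == normalize_text(test),
           !is.na(.data$qualitative), .data$qualitative == .env$wanted) |>
    select("patient_id", "result_date")
}

clause_satisfaction <- function(extract, clause, dictionary) {
  type <- intersect(names(clause), atom_types)
  switch(type,
         problem_terms = sat_problem_terms(extract, clause$problem_terms, dictionary),
         medication = sat_medication(extract, clause$medication),
         lab = sat_lab(extract, clause$lab),
         bp = sat_bp(extract, clause$bp),
         bmi = sat_bmi(extract, clause$bmi),
         lab_med = sat_lab_med(extract, clause$lab_med))
}

#' Identify cases of a condition in a cohort
#'
#' Applies a [case_definition()] to every cohort member: a patient is a case
#' when any clause is satisfied, the onset date is the earliest clause
#' satisfaction date, and an age restriction (if any) is enforced on the index
#' age. Deterministic and per-patient independent.
#'
#' @param extract An [emr_extract()].
#' @param definition A [case_definition()].
#' @param cohort A [complete_case_cohort()] (a subset of the extract's
#'   patients).
#' @param dictionary Term dictionary for [normalize_term()].
#' @return A tibble of class `case_set` with one row per cohort member:
#'   `patient_id`, `is_case`, `onset_date` (`NA` for non-cases); attribute
#'   `condition_id`.
#' @export
identify_cases <- function(extract, definition, cohort,
                           dictionary = term_dictionary()) {
  stopifnot(inherits(extract, "emr_extract"),
            inherits(definition, "case_definition"))
  sats <- purrr::map(definition$clauses, clause_satisfaction,
                     extract = extract, dictionary = dictionary)
  all_sat <- dplyr::bind_rows(sats)
  onset <- if (nrow(all_sat) == 0)
    tibble(patient_id = character(), onset_date = as.Date(character()))
  else
    all_sat |>
      group_by(.data$patient_id) |>
      summarise(onset_date = min(.data$sat_date), .groups = "drop")

  out <- tibble(patient_id = cohort$patient_id) |>
    left_join(onset, by = "patient_id") |>
    mutate(is_case = !is.na(.data$onset_date)) |>
    select("patient_id", "is_case", "onset_date")

  if (!is.null(definition$age_max)) {
    restricted <- cohort$patient_id[cohort$index_age <= definition$age_max]
    out <- out |>
      mutate(is_case = .data$is_case & .data$patient_id %in% restricted,
             onset_date = dplyr::if_else(.data$is_case, .data$onset_date,
                                         as.Date(NA)))
  }
  structure(out, class = c("case_set", class(out)),
            condition_id = definition$condition_id)
}

#' Evaluate a case definition for a single patient
#'
#' Single-patient view of [identify_cases()]: the extract is sliced down to
#' one patient's records before the clauses are applied, so the result cannot
#' depend on any other patient.
#'
#' @inheritParams identify_cases
#' @param patient_id Patient key present in the extract.
#' @param index_date Date at which the age restriction (if any) is evaluated;
#'   defaults to the window start.
#' @return List with `is_case` and `onset_date` (`NA` when not a case).
#' @export
evaluate_case <- function(extract, definition, patient_id, index_date = NULL,
                          dictionary = term_dictionary()) {
  stopifnot(inherits(extract, "emr_extract"))
  if (!patient_id %in% extract$patients$patient_id) {
    abort(sprintf("Unknown patient_id: %s", patient_id))
  }
  index_date <- as.Date(index_date %||% extract$window_start)
  slice_tab <- function(tb) {
    if (is.null(tb)) NULL else tb[tb$patient_id == patient_id, ]
  }
  mini <- extract
  for (nm in record_tables()) mini[[nm]] <- slice_tab(extract[[nm]])
  sats <- purrr::map(definition$clauses, clause_satisfaction,
                     extract = mini, dictionary = dictionary)
  dates <- dplyr::bind_rows(sats)$sat_date
  is_case <- length(dates) > 0
  if (is_case && !is.null(definition$age_max)) {
    birth <- extract$patients$birth_date[
      extract$patients$patient_id == patient_id]
    age <- if (is.na(birth)) NA_integer_ else years_between(birth, index_date)
    is_case <- !is.na(age) && age <= definition$age_max
  }
  list(is_case = is_case,
       onset_date = if (is_case) min(dates) else as.Date(NA))
}

#' Patients with a billing code for a condition
#'
#' @param extract An [emr_extract()].
#' @param condition_id Condition key into `code_map`.
#' @param code_map Named list of character code sets (defaults to the shipped
#'   billing map); codes are matched on exact string after trimming.
#' @param cohort Cohort to restrict to.
#' @return Character vector of patient ids (a subset of the cohort).
#' @export
billing_positives <- function(extract, condition_id,
                              code_map = default_case_definitions()$billing_codes,
                              cohort) {
  codes <- code_map[[condition_id]]
  if (is.null(codes) || length(codes) == 0) {
    abort(sprintf("No billing codes configured for `%s`.", condition_id))
  }
  b <- extract$billing
  if (is.null(b) || nrow(b) == 0) return(character())
  hits <- b$patient_id[trimws(b$diag_code) %in% trimws(codes)]
  intersect(cohort$patient_id, unique(hits))
}

#' Patients on a hypertension medication pattern
#'
#' The group "patients with hypertension medications" (two or more distinct
#' oral anti-hypertensives, or one or more diuretics), together with the date
#' the pattern was first met — used as a denominator for the blood-pressure
#' monitoring measure.
#'
#' @param extract An [emr_extract()].
#' @param cohort Cohort to restrict to.
#' @param definition The hypertension [case_definition()] whose medication
#'   clauses define the pattern (default: the shipped default).
#' @return Tibble `patient_id`, `pattern_date`.
#' @export
hypertension_medication_patients <- function(
    extract, cohort,
    definition = default_case_definitions()$definitions$hypertension) {
  med_clauses <- purrr::keep(definition$clauses,
                             ~ !is.null(.x$medication))
  sats <- purrr::map(med_clauses, ~ sat_medication(extract, .x$medication))
  all_sat <- dplyr::bind_rows(sats)
  if (nrow(all_sat) == 0) {
    return(tibble(patient_id = character(), pattern_date = as.Date(character())))
  }
  all_sat |>
    filter(.data$patient_id %in% cohort$patient_id) |>
    group_by(.data$patient_id) |>
    summarise(pattern_date = min(.data$sat_date), .groups = "drop")
}
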