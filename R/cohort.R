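#' Assign ages to half-open five-year bands
#'
#' Bands are `[0,5), [5,10), ..., [top_band_start, Inf)`, labelled `"0-4"`,
#' `"5-9"`, ..., `"85+"`. The bands partition the non-negative integers:
#' disjoint, exhaustive, and ordered (the result is an ordered factor).
#'
#' @param age Integer ages (years), all `>= 0`.
#' @param band_width Width of each band in years (default 5).
#' @param top_band_start Start of the open-ended top band (default 85).
#' @return Ordered factor of band labels.
#' @examples
#' age_band(c(0, 41, 84, 85))
#' @export
age_band <- function(age, band_width = 5, top_band_start = 85) {
  if (any(!is.na(age) & age < 0)) abort("Ages must be non-negative.")
  starts <- seq(0, top_band_start - band_width, by = band_width)
  labels <- c(sprintf("%d-%d", starts, starts + band_width - 1),
              sprintf("%d+", top_band_start))
  idx <- pmin(floor(age / band_width), length(starts)) + 1L
  factor(labels[idx], levels = labels, ordered = TRUE)
}

#' All band labels for a given banding
#' @inheritParams age_band
#' @return Character vector of labels in order.
#' @export
age_band_levels <- function(band_width = 5, top_band_start = 85) {
  levels(age_band(0L, band_width, top_band_start))
}

#' Complete-case cohort at an index date
#'
#' Restricts the patient roster to patients with complete sex and age
#' information: non-missing sex, non-missing birth date, and a non-negative
#' index age (completed years at the index date). Excluded patients are
#' counted by reason in the `exclusions` attribute; the cohort size plus the
#' exclusion counts always equals the patient-table row count.
#'
#' @param extract An [emr_extract()].
#' @param index_date Date at which index age is computed (default: the window
#'   start, matching the "as of" convention of dataset descriptions).
#' @param band_width,top_band_start Banding passed to [age_band()].
#' @return A tibble of class `emr_cohort` with `patient_id`, `sex`,
#'   `birth_date`, `index_age`, `band`; attributes `index_date` and
#'   `exclusions` (tibble of reason/n).
#' @export
complete_case_cohort <- function(extract, index_date = NULL,
                                 band_width = 5, top_band_start = 85) {
  stopifnot(inherits(extract, "emr_extract"))
  index_date <- as.Date(index_date %||% extract$window_start)

  pts <- extract$patients
  age <- years_between(pts$birth_date, index_date)
  missing_sex <- is.na(pts$sex)
  missing_age <- !missing_sex & is.na(pts$birth_date)
  negative_age <- !missing_sex & !is.na(age) & age < 0

  keep <- !missing_sex & !missing_age & !negative_age
  cohort <- tibble(
    patient_id = pts$patient_id[keep],
    sex = pts$sex[keep],
    birth_date = pts$birth_date[keep],
    index_age = as.integer(age[keep])
  )
  cohort$band <- age_band(cohort$index_age, band_width, top_band_start)

  exclusions <- tibble(
    reason = c("missing_sex", "missing_age", "negative_index_age"),
    n = c(sum(missing_sex), sum(missing_age), sum(negative_age))
  )
  structure(cohort,
            class = c("emr_cohort", class(cohort)),
            index_date = index_date,
            exclusions = exclusions)
}

#' Last visit date per patient
#'
#' @param extract An [emr_extract()].
#' @return Tibble `patient_id`, `last_visit` — one row per patient with at
#'   least one visit; patients without visits are absent.
#' @export
last_visit_dates <- function(extract) {
  stopifnot(inherits(extract, "emr_extract"))
  v <- extract$visits
  if (is.null(v) || nrow(v) == 0) {
    return(tibble(patient_id = character(), last_visit = as.Date(character())))
  }
  v |>
    group_by(.data$patient_id) |>
    summarise(last_visit = max(.data$visit_date), .groups = "drop")
}

#' Last visit date for one patient
#'
#' @param extract An [emr_extract()].
#' @param patient_id A patient key present in the extract.
#' @return A `Date`, or `NA` (class `Date`) when the patient has no visits.
#' @export
last_visit_date <- function(extract, patient_id) {
  stopifnot(inherits(extract, "emr_extract"))
  if (!patient_id %in% extract$patients$patient_id) {
    abort(sprintf("Unknown patient_id: %s", patient_id))
  }
  v <- extract$visits
  if (is.null(v)) return(as.Date(NA))
  d <- v$visit_date[v$patient_id == patient_id]
  if (length(d) == 0) as.Date(NA) else max(d)
}
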