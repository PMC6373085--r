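#' @keywords internal
"_PACKAGE"

# Relational schema of an EMR extract: one row per table, with its date column
# and required columns. The patients table is mandatory; record tables may be
# absent (NULL) when an EMR product does not collect them, which downstream
# measures surface as machine-readable "not computable" reasons.
emr_schema <- function() {
  tibble::tribble(
    ~table,          ~date_col,       ~required_cols,
    "patients",      NA_character_,   list(c("patient_id", "sex", "birth_date")),
    "visits",        "visit_date",    list(c("patient_id", "visit_date")),
    "problems",      "entry_date",    list(c("patient_id", "entry_date", "text")),
    "medications",   "start_date",    list(c("patient_id", "start_date", "name")),
    "labs",          "result_date",   list(c("patient_id", "result_date", "test_code", "value")),
    "vitals",        "measure_date",  list(c("patient_id", "measure_date", "kind", "value")),
    "billing",       "service_date",  list(c("patient_id", "service_date", "diag_code")),
    "immunizations", "given_date",    list(c("patient_id", "given_date", "vaccine")),
    "allergies",     "recorded_date", list(c("patient_id", "recorded_date", "substance"))
  )
}

record_tables <- function() setdiff(emr_schema()$table, "patients")

# Optional columns added (as NA) when absent so every extract has a uniform shape.
optional_cols <- list(
  problems = c(code = "character"),
  medications = c(class_code = "character"),
  labs = c(units = "character", qualitative = "character")
)

#' Marker text for a "no known allergies" entry
#'
#' An allergy-record row whose substance equals this marker still counts as an
#' entry for the consistency-of-capture measure (an explicit negative is
#' information, not absence).
#' @return A string.
#' @export
no_known_allergies <- function() "no known allergies"

vitals_kinds <- c("systolic_bp", "diastolic_bp", "height", "weight")

date_col_of <- function(table) {
  sch <- emr_schema()
  sch$date_col[match(table, sch$table)]
}

#' Construct a validated EMR extract
#'
#' Bundles the relational tables of a practice-database snapshot together with
#' its observation window and validates them: unique patient identifiers,
#' referential integrity of every record table against the patient roster, all
#' event dates on or before the window end, strictly positive vitals values,
#' and known vitals kinds. Exact duplicate rows are removed with a message
#' (measures are counts of patients, not rows). Sex and birth date may be
#' missing but are never imputed.
#'
#' @param patients Tibble with `patient_id`, `sex` (`"male"`, `"female"` or
#'   `NA`) and `birth_date` (`Date` or `NA`).
#' @param visits,problems,medications,labs,vitals,billing,immunizations,allergies
#'   Record tibbles (see the column dictionaries in the package vignette), or
#'   `NULL` for a table the source EMR does not provide.
#' @param window_start,window_end Observation window (dates,
#'   `window_start < window_end`). Records may predate the window start
#'   (historical data carried into the extract) but never follow the end.
#' @param dialect `"structured"` or `"free_text"`: whether problem list and
#'   medication entries carry structured codes or free text only.
#' @return An object of class `emr_extract`: a named list of validated tibbles
#'   plus `window_start`, `window_end` and `dialect`.
#' @examples
#' ex <- emr_extract(
#'   patients = tibble::tibble(
#'     patient_id = "p1", sex = "female", birth_date = as.Date("1970-06-01")
#'   ),
#'   window_start = as.Date("2006-01-01"), window_end = as.Date("2010-12-31")
#' )
#' ex
#' @export
emr_extract <- function(patients,
                        visits = NULL, problems = NULL, medications = NULL,
                        labs = NULL, vitals = NULL, billing = NULL,
                        immunizations = NULL, allergies = NULL,
                        window_start, window_end,
                        dialect = c("structured", "free_text")) {
  dialect <- match.arg(dialect)
  window_start <- assert_date(window_start, "window_start")
  window_end <- assert_date(window_end, "window_end")
  if (window_start >= window_end) {
    abort("`window_start` must be strictly before `window_end`.")
  }

  tables <- list(
    patients = patients, visits = visits, problems = problems,
    medications = medications, labs = labs, vitals = vitals,
    billing = billing, immunizations = immunizations, allergies = allergies
  )
  sch <- emr_schema()
  errors <- character()

  for (nm in sch$table) {
    tb <- tables[[nm]]
    if (is.null(tb)) {
      if (nm == "patients") abort("A patients table is required.")
      next
    }
    tb <- as_tibble(tb)
    req <- sch$required_cols[[match(nm, sch$table)]][[1]]
    missing_cols <- setdiff(req, names(tb))
    if (length(missing_cols) > 0) {
      abort(sprintf("Table `%s` is missing required column(s): %s.",
                    nm, paste(missing_cols, collapse = ", ")))
    }
    for (oc in names(optional_cols[[nm]] %||% character())) {
      if (!oc %in% names(tb)) tb[[oc]] <- NA_character_
    }
    dcol <- sch$date_col[match(nm, sch$table)]
    if (!is.na(dcol)) {
      tb[[dcol]] <- as.Date(tb[[dcol]])
      bad <- which(is.na(tb[[dcol]]))
      if (length(bad) > 0) {
        errors <- c(errors, sprintf(
          "%s: %d row(s) with unparseable/missing date (rows %s).",
          nm, length(bad), paste(utils::head(bad, 5), collapse = ", ")))
      }
      late <- which(!is.na(tb[[dcol]]) & tb[[dcol]] > window_end)
      if (length(late) > 0) {
        errors <- c(errors, sprintf(
          "%s: %d row(s) dated after the window end (rows %s).",
          nm, length(late), paste(utils::head(late, 5), collapse = ", ")))
      }
    }
    if (nm == "patients") {
      tb$patient_id <- as.character(tb$patient_id)
      tb$birth_date <- as.Date(tb$birth_date)
      dup <- tb$patient_id[duplicated(tb$patient_id)]
      if (length(dup) > 0) {
        errors <- c(errors, sprintf(
          "patients: duplicated patient_id(s): %s.",
          paste(utils::head(unique(dup), 5), collapse = ", ")))
      }
      bad_sex <- which(!is.na(tb$sex) & !tb$sex %in% c("male", "female"))
      if (length(bad_sex) > 0) {
        errors <- c(errors, sprintf(
          "patients: %d row(s) with sex outside {male, female, NA} (rows %s).",
          length(bad_sex), paste(utils::head(bad_sex, 5), collapse = ", ")))
      }
    } else {
      tb$patient_id <- as.character(tb$patient_id)
    }
    if (nm == "vitals" && nrow(tb) > 0) {
      bad_kind <- which(!tb$kind %in% vitals_kinds)
      if (length(bad_kind) > 0) {
        errors <- c(errors, sprintf(
          "vitals: %d row(s) with unknown kind (rows %s).",
          length(bad_kind), paste(utils::head(bad_kind, 5), collapse = ", ")))
      }
      bad_val <- which(!is.na(tb$value) & tb$value <= 0)
      if (length(bad_val) > 0) {
        errors <- c(errors, sprintf(
          "vitals: %d row(s) with non-positive value (rows %s).",
          length(bad_val), paste(utils::head(bad_val, 5), collapse = ", ")))
      }
    }
    n0 <- nrow(tb)
    tb <- dplyr::distinct(tb)
    if (nrow(tb) < n0) {
      inform(sprintf("%s: removed %d exact duplicate row(s).", nm, n0 - nrow(tb)))
    }
    tables[[nm]] <- tb
  }

  ids <- tables$patients$patient_id
  for (nm in record_tables()) {
    tb <- tables[[nm]]
    if (is.null(tb) || nrow(tb) == 0) next
    orphan <- which(!tb$patient_id %in% ids)
    if (length(orphan) > 0) {
      errors <- c(errors, sprintf(
        "%s: %d row(s) reference unknown patient_id (rows %s).",
        nm, length(orphan), paste(utils::head(orphan, 5), collapse = ", ")))
    }
  }

  if (length(errors) > 0) {
    abort(c("EMR extract failed validation:", errors))
  }

  structure(
    c(tables,
      list(window_start = window_start, window_end = window_end,
           dialect = dialect)),
    class = "emr_extract"
  )
}

#' @export
print.emr_extract <- function(x, ...) {
  cat(sprintf("<emr_extract> %s to %s (%s dialect)\n",
              format(x$window_start), format(x$window_end), x$dialect))
  for (nm in emr_schema()$table) {
    tb <- x[[nm]]
    cat(sprintf("  %-14s %s\n", nm,
                if (is.null(tb)) "absent" else sprintf("%d rows", nrow(tb))))
  }
  invisible(x)
}

#' Read an EMR extract from a directory of CSV files
#'
#' Expects RFC-4180 CSV files with headers, one per table
#' (`patients.csv`, `visits.csv`, ...); missing record-table files become
#' absent tables. ISO-8601 dates. An `extract_meta.csv` written by
#' [write_emr_extract()] supplies the window and dialect when the arguments are
#' not given. Patient files that supply an integer `age` column instead of
#' `birth_date` get a synthetic mid-year birth date (July 1 of
#' `index year - age`) and an `age_derived` provenance flag.
#'
#' @param dir Directory containing the CSV files.
#' @param window_start,window_end Observation window; defaults to
#'   `extract_meta.csv` when present.
#' @param dialect `"structured"` or `"free_text"`.
#' @param index_date Reference date used only when converting a supplied
#'   integer `age` column into a synthetic birth date (defaults to the window
#'   start).
#' @return An [emr_extract()] object.
#' @export
read_emr_extract <- function(dir, window_start = NULL, window_end = NULL,
                             dialect = NULL, index_date = NULL) {
  meta_path <- file.path(dir, "extract_meta.csv")
  if (file.exists(meta_path)) {
    meta <- readr::read_csv(meta_path, show_col_types = FALSE)
    window_start <- window_start %||% as.Date(meta$window_start[1])
    window_end <- window_end %||% as.Date(meta$window_end[1])
    dialect <- dialect %||% meta$dialect[1]
  }
  if (is.null(window_start) || is.null(window_end)) {
    abort("Supply `window_start`/`window_end` or ship an extract_meta.csv.")
  }
  dialect <- dialect %||% "structured"

  char_cols <- list(
    patients = "sex", problems = c("text", "code"),
    medications = c("name", "class_code"),
    labs = c("test_code", "units", "qualitative"),
    vitals = c("kind", "units"), billing = "diag_code",
    immunizations = "vaccine", allergies = "substance")
  read_one <- function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      if (nm == "patients") abort(sprintf("Required file not found: %s", path))
      return(NULL)
    }
    types <- do.call(readr::cols, c(
      stats::setNames(rep(list(readr::col_character()),
                          1 + length(char_cols[[nm]] %||% character())),
                      c("patient_id", char_cols[[nm]])),
      list(.default = readr::col_guess())))
    readr::read_csv(path, show_col_types = FALSE, col_types = types)
  }

  tabs <- stats::setNames(lapply(emr_schema()$table, read_one), emr_schema()$table)

  pts <- tabs$patients
  if (!"birth_date" %in% names(pts) && "age" %in% names(pts)) {
    idx <- as.Date(index_date %||% window_start)
    pts$birth_date <- dplyr::if_else(
      is.na(pts$age), as.Date(NA),
      as.Date(sprintf("%d-07-01", lubridate::year(idx) - as.integer(pts$age)))
    )
    pts$age_derived <- !is.na(pts$age)
    pts$age <- NULL
    inform("patients: derived synthetic mid-year birth_date from integer age.")
    tabs$patients <- pts
  }

  emr_extract(
    patients = tabs$patients, visits = tabs$visits, problems = tabs$problems,
    medications = tabs$medications, labs = tabs$labs, vitals = tabs$vitals,
    billing = tabs$billing, immunizations = tabs$immunizations,
    allergies = tabs$allergies,
    window_start = window_start, window_end = window_end, dialect = dialect
  )
}

#' Write an EMR extract to a directory of CSV files
#'
#' Inverse of [read_emr_extract()]: writes one CSV per present table plus an
#' `extract_meta.csv` carrying the window and dialect, so that
#' `read_emr_extract(write_emr_extract(x))` round-trips field-for-field.
#'
#' @param extract An [emr_extract()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_emr_extract <- function(extract, dir) {
  stopifnot(inherits(extract, "emr_extract"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in emr_schema()$table) {
    tb <- extract[[nm]]
    if (!is.null(tb)) {
      readr::write_csv(tb, file.path(dir, paste0(nm, ".csv")), na = "")
    }
  }
  readr::write_csv(
    tibble(window_start = extract$window_start,
           window_end = extract$window_end,
           dialect = extract$dialect),
    file.path(dir, "extract_meta.csv")
  )
  invisible(dir)
}
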