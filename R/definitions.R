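conditions_all <- c("diabetes", "hypertension", "hypothyroidism", "asthma",
                    "obesity", "urinary_tract_infection")

atom_types <- c("problem_terms", "medication", "lab", "bp", "bmi", "lab_med")

#' Construct a case definition
#'
#' A case definition is a disjunction of clauses: a patient is a case when any
#' clause is satisfied by their records, and the onset date is the earliest
#' date at which any clause first becomes satisfied. Clause atoms:
#'
#' * `problem_terms` — character vector of canonical tokens matched against
#'   normalized problem-list text (see [normalize_term()]).
#' * `medication` — list with `classes` (class-code prefixes), `names`
#'   (normalized name fragments) and `min_distinct` (distinct qualifying
#'   drugs required; for count rules the clause is satisfied on the date the
#'   `min_distinct`-th distinct drug first appears).
#' * `lab` — list with `test`, and either `op` + `threshold` (+ optional
#'   `units`, enforced against the lab table) or `qualitative = "positive"`.
#' * `bp` — list with `systolic`, `diastolic`, `min_count`: at least
#'   `min_count` distinct dates with a paired blood-pressure reading at or
#'   above either threshold.
#' * `bmi` — list with `threshold`: a same-day height + weight pair giving
#'   BMI (kg/m^2) at or above the threshold.
#' * `lab_med` — a qualitative-positive lab plus a qualifying medication
#'   started within `within_days` days after it.
#'
#' @param condition_id Condition identifier (one of the six test conditions,
#'   or any string for user-defined conditions).
#' @param clauses Non-empty list of clause atoms as above.
#' @param age_max Optional age restriction: only cohort members with
#'   `index_age <= age_max` can be cases (asthma uses 17, i.e. under 18).
#' @return An object of class `case_definition`.
#' @export
case_definition <- function(condition_id, clauses, age_max = NULL) {
  if (length(clauses) == 0) {
    abort("A case definition needs at least one clause.")
  }
  for (cl in clauses) {
    type <- intersect(names(cl), atom_types)
    if (length(type) != 1) {
      abort(sprintf(
        "Each clause must contain exactly one atom type (%s).",
        paste(atom_types, collapse = ", ")))
    }
    if (type == "lab") {
      atom <- cl$lab
      if (is.null(atom$qualitative) &&
          (is.null(atom$op) || is.null(atom$threshold) ||
           !atom$op %in% c(">=", ">", "<=", "<", "=="))) {
        abort("A numeric lab atom needs `op` (one of >=, >, <=, <, ==) and `threshold`.")
      }
    }
  }
  structure(
    list(condition_id = condition_id, clauses = clauses,
         age_max = if (!is.null(age_max)) as.integer(age_max)),
    class = "case_definition"
  )
}

#' @export
print.case_definition <- function(x, ...) {
  cat(sprintf("<case_definition> %s: %d clause(s)%s\n",
              x$condition_id, length(x$clauses),
              if (!is.null(x$age_max))
                sprintf(", restricted to index age <= %d", x$age_max) else ""))
  invisible(x)
}

parse_definition_yaml <- function(doc) {
  defs <- purrr::imap(doc$conditions, function(spec, id) {
    clauses <- purrr::map(spec$clauses, function(cl) {
      if (!is.null(cl$problem_terms)) {
        list(problem_terms = unlist(cl$problem_terms))
      } else cl
    })
    case_definition(id, clauses, age_max = spec$age_max)
  })
  billing <- purrr::map(doc$billing_codes %||% list(),
                        ~ as.character(unlist(.x)))
  list(definitions = defs, billing_codes = billing)
}

#' Read case definitions and billing-code maps from a YAML document
#'
#' @param path YAML file with top-level `conditions:` (each holding `clauses`
#'   and optional `age_max`) and `billing_codes:` sections; see the shipped
#'   default at `system.file("extdata", "default_definitions.yaml",
#'   package = "emrdq")` for the schema.
#' @return List with `definitions` (named list of [case_definition()]) and
#'   `billing_codes` (named list of character code sets).
#' @export
read_case_definitions <- function(path) {
  parse_definition_yaml(yaml::read_yaml(path))
}

the_defaults <- new.env(parent = emptyenv())

#' The shipped default case definitions
#'
#' Editable defaults for the six test conditions, built from problem-list
#' terms, medication classes, laboratory thresholds, blood-pressure readings
#' and BMI. They are starting points calibrated to common clinical practice,
#' not validated phenotyping algorithms; every element lives in the YAML
#' configuration, not in code.
#'
#' @return Same structure as [read_case_definitions()].
#' @export
default_case_definitions <- function() {
  if (is.null(the_defaults$defs)) {
    path <- system.file("extdata", "default_definitions.yaml", package = "emrdq")
    the_defaults$defs <- read_case_definitions(path)
  }
  the_defaults$defs
}
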