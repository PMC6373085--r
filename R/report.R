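#' Assessment configuration
#'
#' Tunable settings for [run_assessment()]. Windows are in days; "12 months"
#' and "1 year" default to 365, "two months" to a fixed 62-day window
#' (calendar-month arithmetic is ambiguous across month lengths).
#'
#' @param index_date Index date for the cohort (default: window start).
#' @param age_breaks Age-group lower bounds for stratified chi-squares.
#' @param bp_min_age Minimum age for blood-pressure denominators (default 18).
#' @param bp_onset_window_days Monitoring window after onset (default 365).
#' @param vitals_window_days Timeliness window before the last visit
#'   (default 365).
#' @param pregnancy_window_days Follow-up window after a positive pregnancy
#'   test (default 62).
#' @param final_year_days "Last year of the database" window (default 365).
#' @param suppression_threshold Rendered counts below this are suppressed
#'   (default 5; 0 disables).
#' @param by_sex Standardize prevalence over age-by-sex strata (default) or
#'   age only.
#' @param conf_level Confidence level for standardized-rate intervals.
#' @param lenient_bp Count single-component blood-pressure rows.
#' @param vaccination_min_age Age threshold for the unlikely-vaccination
#'   check.
#' @param reference_prevalence Named list of published prevalence figures
#'   (percent) echoed next to computed prevalences, never recomputed.
#' @return List of class `dq_config`.
#' @export
dq_config <- function(index_date = NULL,
                      age_breaks = c(0, 18, 45, 60),
                      bp_min_age = 18,
                      bp_onset_window_days = 365,
                      vitals_window_days = 365,
                      pregnancy_window_days = 62,
                      final_year_days = 365,
                      suppression_threshold = 5,
                      by_sex = TRUE,
                      conf_level = 0.95,
                      lenient_bp = FALSE,
                      vaccination_min_age = 10,
                      reference_prevalence = list(
                        diabetes = 6.8, hypertension = 19.1,
                        hypothyroidism = 7.1, asthma = 21.1, obesity = 24.1,
                        urinary_tract_infection = NA_real_)) {
  structure(as.list(environment()), class = "dq_config")
}

table_present <- function(extract, nm) !is.null(extract[[nm]])

clause_tables <- function(clause) {
  type <- intersect(names(clause), atom_types)
  switch(type,
         problem_terms = "problems",
         medication = "medications",
         lab = "labs",
         bp = "vitals",
         bmi = "vitals",
         lab_med = c("labs", "medications"))
}

# Drop clauses whose source tables are absent; NULL when nothing is left.
usable_definition <- function(extract, definition) {
  keep <- purrr::keep(definition$clauses, function(cl)
    all(vapply(clause_tables(cl), table_present, logical(1),
               extract = extract)))
  dropped <- length(definition$clauses) - length(keep)
  if (length(keep) == 0) {
    return(list(definition = NULL, dropped = dropped))
  }
  list(definition = case_definition(definition$condition_id, keep,
                                    age_max = definition$age_max),
       dropped = dropped)
}

not_computable <- function(domain, family, measure, reason,
                           condition_id = NA_character_) {
  tibble(domain = domain, family = family, measure = measure,
         condition_id = condition_id, numerator = NA_integer_,
         denominator = NA_integer_, value_pct = NA_real_, undefined = FALSE,
         not_computable = TRUE, reason = reason)
}

#' Run the full four-domain data-quality assessment
#'
#' Computes the eleven measure families — population comparability, mean and
#' median age, prevalence concordance, billing sensitivity, consistency of
#' capture, vitals recording, blood-pressure monitoring, billing positive
#' predictive value, unlikely vaccination, and the three timeliness measures
#' — over a complete-case cohort. Measures whose source tables the extract
#' does not provide are reported with machine-readable reasons, never
#' silently omitted; conditions whose definitions lose clauses to missing
#' tables are marked degraded. Deterministic: identical inputs give an
#' identical report.
#'
#' @param extract An [emr_extract()].
#' @param definitions Output of [read_case_definitions()] (default: the
#'   shipped defaults).
#' @param standard A `standard_population`.
#' @param config A [dq_config()].
#' @return An object of class `dq_report`: `results` (one tibble row per
#'   measure with counts, percentages, tests and flags) and `meta`
#'   (cohort size, exclusions, config hash, window).
#' @export
run_assessment <- function(extract,
                           definitions = default_case_definitions(),
                           standard = standard_population(),
                           config = dq_config()) {
  stopifnot(inherits(extract, "emr_extract"))
  cohort <- complete_case_cohort(extract, config$index_date)
  if (nrow(cohort) == 0) abort("No complete cases: cannot assess an empty cohort.")

  rows <- list()
  notes <- character()

  # case identification, with degradation bookkeeping
  case_sets <- list()
  degraded <- list()
  for (cid in names(definitions$definitions)) {
    us <- usable_definition(extract, definitions$definitions[[cid]])
    degraded[[cid]] <- us$dropped
    if (is.null(us$definition)) {
      case_sets[cid] <- list(NULL)
    } else {
      case_sets[[cid]] <- identify_cases(extract, us$definition, cohort)
    }
  }
  cond_reason <- function(cid) {
    sprintf("definition for %s not computable: all clauses reference absent tables", cid)
  }
  cond_note <- function(cid) {
    if (degraded[[cid]] > 0 && !is.null(case_sets[[cid]]))
      sprintf("definition degraded: %d clause(s) dropped (absent tables)",
              degraded[[cid]])
    else NA_character_
  }

  # --- comparability ----------------------------------------------------
  chs <- chi_square_vs_standard(age_sex_table(cohort), standard)
  rows$pop <- tibble(
    domain = "comparability", family = "population_vs_standard",
    measure = "age_sex_chi_square", condition_id = NA_character_,
    numerator = NA_integer_, denominator = as.integer(nrow(cohort)),
    value_pct = NA_real_, statistic = chs$statistic,
    df = as.integer(chs$df), p_value = chs$p_value,
    n_pooled = as.integer(chs$n_pooled), undefined = FALSE)
  mm <- mean_median_age(cohort)
  rows$age <- tibble(
    domain = "comparability", family = "population_vs_standard",
    measure = "mean_median_age", condition_id = mm$sex,
    numerator = NA_integer_, denominator = as.integer(mm$n),
    value_pct = NA_real_, mean_age = mm$mean_age, median_age = mm$median_age,
    undefined = FALSE)

  prev_rows <- list()
  for (cid in names(definitions$definitions)) {
    cs <- case_sets[[cid]]
    if (is.null(cs)) {
      prev_rows[[cid]] <- not_computable("comparability", "prevalence",
                                         "prevalence", cond_reason(cid), cid)
      next
    }
    def <- definitions$definitions[[cid]]
    ref <- config$reference_prevalence[[cid]] %||% NA_real_
    if (!is.null(def$age_max)) {
      sub <- cohort[cohort$index_age <= def$age_max, ]
      sub_cs <- cs[cs$patient_id %in% sub$patient_id, ]
      prev_rows[[cid]] <- tibble(
        domain = "comparability", family = "prevalence",
        measure = "prevalence_crude_only", condition_id = cid,
        numerator = as.integer(sum(sub_cs$is_case)),
        denominator = as.integer(nrow(sub)),
        value_pct = pct_raw(sum(sub_cs$is_case), nrow(sub)),
        reference_pct = ref, undefined = nrow(sub) == 0,
        note = paste("not age standardized: definition limited to index age",
                     "<=", def$age_max))
    } else {
      pr <- standardized_prevalence(cs, cohort, standard,
                                    by_sex = config$by_sex,
                                    conf_level = config$conf_level,
                                    reference_pct = ref)
      prev_rows[[cid]] <- tibble(
        domain = "comparability", family = "prevalence",
        measure = "prevalence", condition_id = cid,
        numerator = as.integer(pr$n_cases), denominator = as.integer(pr$n),
        value_pct = pr$crude_pct, standardized_pct = pr$standardized_pct,
        ci_low = pr$ci_low, ci_high = pr$ci_high,
        reference_pct = pr$reference_pct, undefined = FALSE,
        note = cond_note(cid))
    }
  }
  rows$prevalence <- bind_rows(prev_rows)

  # --- completeness -----------------------------------------------------
  billing_ok <- table_present(extract, "billing")
  conc <- function(kind, fun, domain) {
    out <- list()
    for (cid in names(definitions$definitions)) {
      if (!billing_ok) {
        out[[cid]] <- not_computable(domain, kind, kind,
                                     "billing table absent", cid)
      } else if (is.null(case_sets[[cid]])) {
        out[[cid]] <- not_computable(domain, kind, kind, cond_reason(cid), cid)
      } else {
        bp_ids <- billing_positives(extract, cid, definitions$billing_codes,
                                    cohort)
        r <- fun(case_sets[[cid]], bp_ids)
        r$family <- kind
        r$note <- cond_note(cid)
        out[[cid]] <- r
      }
    }
    bind_rows(out)
  }
  rows$sensitivity <- conc("sensitivity", sensitivity_vs_billing, "completeness")

  cc <- consistency_of_capture(extract, cohort, config$final_year_days)
  cc$family <- "consistency_of_capture"
  absent_cc <- c(problem_list = "problems", allergy_record = "allergies",
                 medications = "medications")
  for (m in names(absent_cc)) {
    if (!table_present(extract, absent_cc[[m]])) {
      cc <- cc[cc$measure != m, ]
      cc <- bind_rows(cc, not_computable(
        "completeness", "consistency_of_capture", m,
        sprintf("%s table absent", absent_cc[[m]])))
    }
  }
  rows$consistency <- cc

  vit <- function(fun, family, domain) {
    if (!table_present(extract, "vitals")) {
      return(bind_rows(lapply(c("bp", "height", "weight"), function(k)
        not_computable(domain, family, paste0(family, "_", k),
                       "vitals table absent", k))))
    }
    out <- lapply(c("bp", "height", "weight"), function(k) {
      r <- fun(k)
      r$family <- family
      r
    })
    bind_rows(out)
  }
  rows$vitrec <- vit(function(k)
    vitals_recording(extract, cohort, k, config$age_breaks,
                     config$lenient_bp, config$bp_min_age),
    "vitals_recording", "completeness")

  if (!table_present(extract, "vitals")) {
    rows$bpreq <- bind_rows(
      not_computable("completeness", "bp_among_requiring",
                     "bp_after_diabetes_onset", "vitals table absent",
                     "diabetes"),
      not_computable("completeness", "bp_among_requiring",
                     "bp_after_hypertension_onset", "vitals table absent",
                     "hypertension_meds"))
  } else if (is.null(case_sets$diabetes)) {
    rows$bpreq <- not_computable("completeness", "bp_among_requiring",
                                 "bp_after_diabetes_onset",
                                 cond_reason("diabetes"), "diabetes")
  } else {
    ht_med <- if (table_present(extract, "medications")) {
      hypertension_medication_patients(
        extract, cohort, definitions$definitions$hypertension)
    } else tibble(patient_id = character(), pattern_date = as.Date(character()))
    ht_onset <- if (!is.null(case_sets$hypertension)) {
      ht_med |>
        left_join(select(case_sets$hypertension, "patient_id", "onset_date"),
                  by = "patient_id") |>
        mutate(onset_date = dplyr::coalesce(.data$onset_date,
                                            .data$pattern_date)) |>
        select("patient_id", "onset_date")
    } else rename(ht_med, onset_date = "pattern_date")
    br <- bp_among_requiring(extract, case_sets$diabetes, ht_onset,
                             config$bp_onset_window_days, config$lenient_bp)
    br$family <- "bp_among_requiring"
    rows$bpreq <- br
  }

  # --- correctness ------------------------------------------------------
  rows$ppv <- conc("ppv", ppv_vs_billing, "correctness")

  rows$vacc <- if (!table_present(extract, "immunizations")) {
    not_computable("correctness", "unlikely_vaccination",
                   "unlikely_vaccination", "immunizations table absent")
  } else {
    r <- unlikely_vaccination(extract, cohort,
                              min_age = config$vaccination_min_age)
    r$family <- "unlikely_vaccination"
    r
  }

  # --- currency ---------------------------------------------------------
  rows$wto <- if (!table_present(extract, "vitals")) {
    not_computable("currency", "weight_timeliness_obesity",
                   "weight_timeliness_obesity", "vitals table absent",
                   "obesity")
  } else if (is.null(case_sets$obesity)) {
    not_computable("currency", "weight_timeliness_obesity",
                   "weight_timeliness_obesity", cond_reason("obesity"),
                   "obesity")
  } else {
    r <- weight_timeliness_obesity(extract, case_sets$obesity,
                                   config$vitals_window_days)
    r$family <- "weight_timeliness_obesity"
    r
  }

  rows$preg <- if (!table_present(extract, "labs")) {
    not_computable("currency", "pregnancy_followup", "pregnancy_followup",
                   "labs table absent")
  } else {
    r <- pregnancy_followup(extract, cohort,
                            window_days = config$pregnancy_window_days)
    r$family <- "pregnancy_followup"
    r
  }

  rows$vittime <- vit(function(k)
    vitals_timeliness(extract, cohort, k, config$vitals_window_days,
                      config$age_breaks, config$lenient_bp, config$bp_min_age),
    "vitals_timeliness", "currency")

  results <- bind_rows(rows)
  if (!"not_computable" %in% names(results)) results$not_computable <- FALSE
  results$not_computable <- tidyr::replace_na(results$not_computable, FALSE)
  results$undefined <- tidyr::replace_na(results$undefined, FALSE)
  results$suppressed <- FALSE
  domain_order <- c("comparability", "completeness", "correctness", "currency")
  results <- results |>
    mutate(domain = factor(.data$domain, levels = domain_order)) |>
    arrange(.data$domain) |>
    mutate(domain = as.character(.data$domain))

  report <- structure(
    list(results = results,
         meta = list(
           cohort_n = nrow(cohort),
           exclusions = attr(cohort, "exclusions"),
           index_date = attr(cohort, "index_date"),
           window_start = extract$window_start,
           window_end = extract$window_end,
           dialect = extract$dialect,
           suppression_threshold = config$suppression_threshold,
           config_hash = rlang::hash(unclass(config)))),
    class = "dq_report")
  suppress_small_cells(report, config$suppression_threshold)
}

#' Flag small cells for suppression
#'
#' Marks measures whose numerator is strictly between 0 and `threshold` for
#' suppression. Suppression is render-only: the report object keeps exact
#' counts (so downstream computation is unaffected) and [render_report()]
#' masks flagged values in human-readable output; zero numerators render as
#' 0.0, matching the convention that an exact zero is reportable.
#'
#' @param report A `dq_report`.
#' @param threshold Cell-size threshold (default 5; 0 disables suppression).
#' @return The report with updated `suppressed` flags.
#' @export
suppress_small_cells <- function(report, threshold = 5) {
  stopifnot(inherits(report, "dq_report"), threshold >= 0)
  r <- report$results
  r$suppressed <- !is.na(r$numerator) & r$numerator > 0 &
    r$numerator < threshold
  report$results <- r
  report$meta$suppression_threshold <- threshold
  report
}

rendered_value <- function(results) {
  dplyr::case_when(
    results$not_computable ~ "not computable",
    results$suppressed ~ "*",
    results$undefined ~ "undefined",
    is.na(results$value_pct) ~ "",
    TRUE ~ sprintf("%.1f", round_half_up(results$value_pct, 1))
  )
}

rendered_count <- function(n, suppressed) {
  dplyr::case_when(is.na(n) ~ "", suppressed ~ "*", TRUE ~ as.character(n))
}

#' Render a data-quality report to files
#'
#' Writes the report grouped by domain in comparability, completeness,
#' correctness, currency order. The JSON rendering is lossless (exact counts
#' retained behind the `suppressed` flag); CSV and markdown mask suppressed
#' cells with `*`, render undefined measures as `undefined` (never 0% or
#' 100%), print percentages half-up to one decimal and p-values below 0.001
#' as `<0.001`.
#'
#' @param report A `dq_report`.
#' @param dir Output directory.
#' @param formats Subset of `"json"`, `"csv"`, `"markdown"`.
#' @return Named character vector of written paths, invisibly.
#' @export
render_report <- function(report, dir, formats = c("json", "csv", "markdown")) {
  stopifnot(inherits(report, "dq_report"))
  unknown <- setdiff(formats, c("json", "csv", "markdown"))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown format(s): %s.", paste(unknown, collapse = ", ")))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character()

  if ("json" %in% formats) {
    path <- file.path(dir, "dq_report.json")
    jsonlite::write_json(
      list(meta = report$meta, results = report$results),
      path, auto_unbox = TRUE, digits = NA, null = "null", na = "null",
      Date = "ISO8601", pretty = TRUE)
    out["json"] <- path
  }

  rendered <- report$results |>
    mutate(value = rendered_value(report$results),
           numerator_rendered = rendered_count(.data$numerator,
                                               .data$suppressed)) |>
    select("domain", "family", "measure", "condition_id",
           "numerator_rendered", "denominator", "value",
           dplyr::any_of(c("standardized_pct", "ci_low", "ci_high",
                           "reference_pct", "statistic", "df", "p_value",
                           "mean_age", "median_age", "p_sex", "p_age",
                           "reason", "note")))

  if ("csv" %in% formats) {
    path <- file.path(dir, "dq_report.csv")
    readr::write_csv(rendered, path, na = "")
    out["csv"] <- path
  }

  if ("markdown" %in% formats) {
    path <- file.path(dir, "dq_report.md")
    lines <- c("# EMR data quality report", "")
    for (dom in c("comparability", "completeness", "correctness", "currency")) {
      dom_title <- paste0(toupper(substring(dom, 1, 1)), substring(dom, 2))
      lines <- c(lines, sprintf("## %s", dom_title), "",
                 "| Measure | Condition | n/N | Value (%) | Detail |",
                 "|---|---|---|---|---|")
      sub <- rendered[rendered$domain == dom, ]
      res <- report$results[report$results$domain == dom, ]
      for (i in seq_len(nrow(sub))) {
        detail <- character()
        if ("statistic" %in% names(res) && !is.na(res$statistic[i])) {
          detail <- c(detail, sprintf("chi-sq %.2f (df %d), p %s",
                                      res$statistic[i], res$df[i],
                                      format_p(res$p_value[i])))
        }
        if ("mean_age" %in% names(res) && !is.na(res$mean_age[i])) {
          detail <- c(detail, sprintf("mean %.1f (median %.1f)",
                                      res$mean_age[i], res$median_age[i]))
        }
        if ("standardized_pct" %in% names(res) && !is.na(res$standardized_pct[i])) {
          detail <- c(detail, sprintf(
            "age-standardized %.1f (95%% CI %.1f-%.1f)",
            round_half_up(res$standardized_pct[i], 1),
            round_half_up(res$ci_low[i], 1), round_half_up(res$ci_high[i], 1)))
        }
        if ("p_sex" %in% names(res) && !is.na(res$p_sex[i])) {
          detail <- c(detail, sprintf("p(sex) %s, p(age) %s",
                                      format_p(res$p_sex[i]),
                                      format_p(res$p_age[i])))
        }
        if ("reason" %in% names(res) && !is.na(res$reason[i])) {
          detail <- c(detail, res$reason[i])
        }
        nn <- if (sub$numerator_rendered[i] == "" && is.na(sub$denominator[i]))
          "" else sprintf("%s/%s", sub$numerator_rendered[i],
                          ifelse(is.na(sub$denominator[i]), "",
                                 sub$denominator[i]))
        lines <- c(lines, sprintf(
          "| %s | %s | %s | %s | %s |",
          sub$measure[i],
          ifelse(is.na(sub$condition_id[i]), "", sub$condition_id[i]),
          nn, sub$value[i], paste(detail, collapse = "; ")))
      }
      lines <- c(lines, "")
    }
    writeLines(lines, path)
    out["markdown"] <- path
  }
  invisible(out)
}

#' Read back a JSON-rendered report
#'
#' @param path Path written by [render_report()].
#' @return A `dq_report` equal to the rendered one.
#' @export
read_dq_report_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  results <- as_tibble(raw$results)
  for (col in intersect(c("onset_date"), names(results))) {
    results[[col]] <- as.Date(results[[col]])
  }
  meta <- raw$meta
  meta$exclusions <- as_tibble(meta$exclusions)
  for (col in c("index_date", "window_start", "window_end")) {
    meta[[col]] <- as.Date(meta[[col]])
  }
  structure(list(results = results, meta = meta), class = "dq_report")
}

#' @export
print.dq_report <- function(x, ...) {
  cat(sprintf("<dq_report> cohort n = %d, window %s to %s\n",
              x$meta$cohort_n, format(x$meta$window_start),
              format(x$meta$window_end)))
  cat(sprintf("  %d measures (%d undefined, %d suppressed, %d not computable)\n",
              nrow(x$results), sum(x$results$undefined),
              sum(x$results$suppressed), sum(x$results$not_computable)))
  invisible(x)
}

#' Tidy a data-quality report
#'
#' @param x A `dq_report`.
#' @param ... Unused.
#' @return The measure tibble (one row per measure, with counts, raw
#'   percentages, tests and flags).
#' @export
tidy.dq_report <- function(x, ...) x$results

#' One-row summary of a data-quality report
#'
#' @param x A `dq_report`.
#' @param ... Unused.
#' @return Tibble with cohort size and measure counts.
#' @export
glance.dq_report <- function(x, ...) {
  tibble(cohort_n = x$meta$cohort_n,
         n_measures = nrow(x$results),
         n_undefined = sum(x$results$undefined),
         n_suppressed = sum(x$results$suppressed),
         n_not_computable = sum(x$results$not_computable))
}

#' Plot a data-quality report
#'
#' Bar chart of measure percentages faceted by domain; undefined,
#' suppressed and not-computable measures are omitted from the panel.
#'
#' @param object A `dq_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dq_report <- function(object, ...) {
  d <- object$results |>
    filter(!is.na(.data$value_pct), !.data$suppressed) |>
    mutate(label = ifelse(is.na(.data$condition_id), .data$measure,
                          paste(.data$measure, .data$condition_id, sep = ": ")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value_pct,
                                  y = stats::reorder(.data$label,
                                                     .data$value_pct))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$domain), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "Value (%)", y = NULL,
                  title = "EMR data quality measures") +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
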