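#' Read a standard population table
#'
#' @param path CSV with columns `age_band`, `sex`, `count`.
#' @param name,year Optional metadata attached as attributes.
#' @return Tibble of class `standard_population`.
#' @export
read_standard_population <- function(path, name = NULL, year = NULL) {
  sp <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          age_band = readr::col_character(),
                          sex = readr::col_character(),
                          count = readr::col_double()))
  as_standard_population(sp, name = name %||% basename(path), year = year)
}

#' Coerce a tibble to a standard population
#'
#' @param x Tibble with `age_band`, `sex`, `count` (counts `>= 0`, at least
#'   one positive; bands must use the [age_band()] labels).
#' @param name,year Metadata.
#' @return Tibble of class `standard_population`.
#' @export
as_standard_population <- function(x, name = "standard", year = NULL) {
  x <- as_tibble(x)
  stopifnot(all(c("age_band", "sex", "count") %in% names(x)))
  if (any(x$count < 0) || sum(x$count) <= 0) {
    abort("Standard population counts must be >= 0 with at least one positive cell.")
  }
  bad <- setdiff(unique(x$age_band), age_band_levels())
  if (length(bad) > 0) {
    abort(sprintf("Unknown age band label(s) in standard population: %s.",
                  paste(bad, collapse = ", ")))
  }
  x$age_band <- factor(x$age_band, levels = age_band_levels(), ordered = TRUE)
  structure(arrange(x, .data$sex, .data$age_band),
            class = c("standard_population", class(x)),
            name = name, year = year)
}

#' The bundled synthetic standard population
#'
#' A synthetic age-sex structure loosely shaped like a national census,
#' shipped so examples and tests run without external data. For real
#' assessments supply your own census table via [read_standard_population()].
#'
#' @return A `standard_population` tibble.
#' @export
standard_population <- function() {
  read_standard_population(
    system.file("extdata", "standard_population_synthetic.csv",
                package = "emrdq"),
    name = "synthetic census-like standard")
}

#' Age-sex contingency table of a cohort
#'
#' @param cohort A [complete_case_cohort()].
#' @param band_width,top_band_start Banding passed to [age_band()].
#' @return Tibble `age_band`, `sex`, `n`, complete over all band-sex cells
#'   (zero-filled); cell counts sum to the cohort size.
#' @export
age_sex_table <- function(cohort, band_width = 5, top_band_start = 85) {
  if (nrow(cohort) == 0) abort("Cannot tabulate an empty cohort.")
  cohort |>
    mutate(age_band = age_band(.data$index_age, band_width, top_band_start)) |>
    count(.data$age_band, .data$sex, name = "n") |>
    tidyr::complete(
      age_band = factor(age_band_levels(band_width, top_band_start),
                        levels = age_band_levels(band_width, top_band_start),
                        ordered = TRUE),
      sex = c("female", "male"),
      fill = list(n = 0L)) |>
    arrange(.data$sex, .data$age_band)
}

# Pool adjacent age bands (within sex) until every expected count reaches
# `min_expected`; a trailing short group is folded into its predecessor.
pool_cells <- function(cells, min_expected = 5) {
  pooled <- cells |>
    group_by(.data$sex) |>
    group_modify(function(d, key) {
      d <- arrange(d, .data$age_band)
      grp <- integer(nrow(d))
      g <- 1L
      acc <- 0
      for (i in seq_len(nrow(d))) {
        grp[i] <- g
        acc <- acc + d$expected[i]
        if (acc >= min_expected && i < nrow(d)) {
          g <- g + 1L
          acc <- 0
        }
      }
      if (acc < min_expected && g > 1L) grp[grp == g] <- g - 1L
      d$grp <- grp
      d
    }) |>
    ungroup() |>
    group_by(.data$sex, .data$grp) |>
    summarise(observed = sum(.data$observed),
              expected = sum(.data$expected), .groups = "drop")
  pooled
}

#' Chi-square goodness of fit of a cohort's age-sex structure to a standard
#'
#' Expected counts are the standard population's cell proportions scaled to
#' the observed total (so the statistic is invariant to the absolute size of
#' the standard). Cells with expected counts below `min_expected` are pooled
#' into adjacent age bands within sex before the test, with the number of
#' pooled cells reported; degrees of freedom are the number of cells after
#' pooling minus one.
#'
#' @param observed Output of [age_sex_table()] (columns `age_band`, `sex`,
#'   `n`), or a cohort, in which case the table is built first.
#' @param standard A `standard_population` covering all observed cells.
#' @param min_expected Pooling threshold for expected counts (default 5).
#' @return List of class `dq_chisq`: `statistic`, `df`, `p_value`,
#'   `n_pooled`, and the pooled `cells` tibble.
#' @export
chi_square_vs_standard <- function(observed, standard, min_expected = 5) {
  if (inherits(observed, "emr_cohort")) observed <- age_sex_table(observed)
  std <- standard |>
    group_by(age_band = .data$age_band, sex = .data$sex) |>
    summarise(std_count = sum(.data$count), .groups = "drop")
  if (sum(std$std_count) <= 0) abort("Standard population is all zero.")

  cells <- observed |>
    rename(observed = "n") |>
    left_join(std, by = c("age_band", "sex")) |>
    mutate(std_count = tidyr::replace_na(.data$std_count, 0))
  uncovered <- cells |> filter(.data$observed > 0, .data$std_count == 0)
  if (nrow(uncovered) > 0) {
    abort("Standard population does not cover all observed cells.")
  }
  total <- sum(cells$observed)
  cells <- cells |>
    mutate(expected = .data$std_count / sum(.data$std_count) * total) |>
    filter(.data$std_count > 0)

  pooled <- pool_cells(cells, min_expected)
  n_pooled <- nrow(cells) - nrow(pooled)
  test <- stats::chisq.test(x = pooled$observed,
                            p = pooled$expected / sum(pooled$expected))
  structure(
    list(statistic = unname(test$statistic), df = unname(test$parameter),
         p_value = unname(test$p.value), n_pooled = n_pooled, cells = pooled),
    class = "dq_chisq")
}

#' @export
print.dq_chisq <- function(x, ...) {
  cat(sprintf("Chi-square = %.3f, df = %d, p %s%s\n",
              x$statistic, x$df,
              if (x$p_value < 0.001) "< 0.001" else sprintf("= %.4f", x$p_value),
              if (x$n_pooled > 0)
                sprintf(" (%d cell(s) pooled)", x$n_pooled) else ""))
  invisible(x)
}

#' Mean and median index age, by sex and overall
#'
#' @param cohort A non-empty [complete_case_cohort()].
#' @return Tibble `sex` (`"female"`, `"male"`, `"overall"`), `n`, `mean_age`,
#'   `median_age` (even-sized groups use the midpoint convention).
#' @export
mean_median_age <- function(cohort) {
  if (nrow(cohort) == 0) abort("Cannot summarise an empty cohort.")
  by_sex <- cohort |>
    group_by(.data$sex) |>
    summarise(n = dplyr::n(), mean_age = mean(.data$index_age),
              median_age = stats::median(.data$index_age), .groups = "drop")
  overall <- cohort |>
    summarise(sex = "overall", n = dplyr::n(), mean_age = mean(.data$index_age),
              median_age = stats::median(.data$index_age))
  bind_rows(by_sex, overall)
}

# Gamma (Fay-Feuer) confidence interval for a directly standardized rate.
# w: normalized stratum weights; events: stratum case counts; n: stratum
# denominators. Rates on the 0-1 scale.
gamma_ci <- function(w, events, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  y <- sum(w * events / n)
  v <- sum(w^2 * events / n^2)
  w_max <- max(w / n)
  lower <- if (y == 0) 0 else
    stats::qgamma(alpha / 2, shape = y^2 / v, scale = v / y)
  upper <- stats::qgamma(1 - alpha / 2,
                         shape = (y + w_max)^2 / (v + w_max^2),
                         scale = (v + w_max^2) / (y + w_max))
  c(lower, upper)
}

#' Crude and directly age-standardized prevalence
#'
#' Crude prevalence is `100 * cases / cohort`. The standardized figure is the
#' direct standardization `sum(w_s * r_s)` over strata `s` (five-year age band
#' by sex by default, age-only with `by_sex = FALSE`), where `w_s` is the
#' standard population's stratum share and `r_s` the stratum-specific
#' prevalence in the cohort. Strata with no cohort members are dropped and the
#' remaining weights renormalized (the number of such strata is reported).
#' The 95% confidence interval for the standardized rate is the gamma
#' (Fay–Feuer) interval.
#'
#' @param cases A `case_set` from [identify_cases()] (all cases must be cohort
#'   members).
#' @param cohort A non-empty [complete_case_cohort()].
#' @param standard A `standard_population`.
#' @param by_sex Standardize over age-by-sex strata (default) or age only.
#' @param conf_level Confidence level (default 0.95).
#' @param reference_pct Optional published prevalence echoed in the result,
#'   never recomputed.
#' @return One-row tibble: `condition_id`, `n_cases`, `n`, `crude_pct`,
#'   `standardized_pct`, `ci_low`, `ci_high`, `reference_pct`,
#'   `n_empty_strata`.
#' @export
standardized_prevalence <- function(cases, cohort, standard, by_sex = TRUE,
                                    conf_level = 0.95, reference_pct = NA_real_) {
  if (nrow(cohort) == 0) abort("Cannot standardize over an empty cohort.")
  if (!all(cases$patient_id[cases$is_case] %in% cohort$patient_id)) {
    abort("Every case must be a cohort member.")
  }
  condition <- attr(cases, "condition_id") %||% NA_character_

  dat <- cohort |>
    left_join(select(cases, "patient_id", "is_case"), by = "patient_id") |>
    mutate(is_case = tidyr::replace_na(.data$is_case, FALSE),
           age_band = age_band(.data$index_age))

  grouping <- if (by_sex) c("age_band", "sex") else "age_band"
  strata <- dat |>
    group_by(dplyr::across(dplyr::all_of(grouping))) |>
    summarise(events = sum(.data$is_case), n = dplyr::n(), .groups = "drop")

  std <- standard |>
    group_by(dplyr::across(dplyr::all_of(grouping))) |>
    summarise(std_count = sum(.data$count), .groups = "drop")

  joined <- std |> left_join(strata, by = grouping)
  n_empty <- sum(is.na(joined$n) | joined$n == 0)
  joined <- joined |> filter(!is.na(.data$n), .data$n > 0)
  w <- joined$std_count / sum(joined$std_count)

  crude <- 100 * sum(dat$is_case) / nrow(dat)
  std_rate <- sum(w * joined$events / joined$n)
  ci <- gamma_ci(w, joined$events, joined$n, conf_level)

  tibble(
    condition_id = condition,
    n_cases = sum(dat$is_case), n = nrow(dat),
    crude_pct = crude,
    standardized_pct = 100 * std_rate,
    ci_low = 100 * ci[1], ci_high = 100 * ci[2],
    reference_pct = reference_pct,
    n_empty_strata = n_empty
  )
}
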