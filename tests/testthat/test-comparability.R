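test_that("age-sex tabulation counts and conserves the cohort", {
  cohort <- make_cohort(c(3, 3, 87), c("male", "male", "female"))
  tab <- age_sex_table(cohort)
  expect_equal(tab$n[tab$age_band == "0-4" & tab$sex == "male"], 2L)
  expect_equal(tab$n[tab$age_band == "85+" & tab$sex == "female"], 1L)
  expect_equal(sum(tab$n), nrow(cohort))
  expect_error(age_sex_table(make_cohort(integer(), character())), "empty")
})

test_that("age-sex tabulation matches a brute-force group-by", {
  s <- small_synth(n = 1000, seed = 13)
  cohort <- complete_case_cohort(s$extract)
  tab <- age_sex_table(cohort)
  bf <- table(as.character(age_band(cohort$index_age)), cohort$sex)
  for (i in seq_len(nrow(tab))) {
    b <- as.character(tab$age_band[i]); s_ <- tab$sex[i]
    bf_n <- if (b %in% rownames(bf) && s_ %in% colnames(bf)) bf[b, s_] else 0L
    expect_equal(tab$n[i], as.integer(bf_n))
  }
})

two_cell_observed <- function(o1, o2) {
  tibble::tibble(
    age_band = factor(c("20-24", "25-29"), levels = age_band_levels(),
                      ordered = TRUE),
    sex = "male", n = c(o1, o2))
}
two_cell_standard <- function(c1, c2) {
  as_standard_population(tibble::tibble(
    age_band = c("20-24", "25-29"), sex = "male", count = c(c1, c2)))
}

test_that("chi-square against the standard matches the closed form", {
  # observed (60, 40) vs a 50/50 standard: sum((O-E)^2/E) = 4, df 1
  r <- chi_square_vs_standard(two_cell_observed(60, 40),
                              two_cell_standard(50, 50))
  expect_equal(r$statistic, 4.0, tolerance = 1e-12)
  expect_equal(r$df, 1)
  expect_equal(r$p_value, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  oracle <- bf_chisq_gof(c(60, 40), c(50, 50))
  expect_equal(r$statistic, oracle$statistic, tolerance = 1e-12)
  expect_equal(r$p_value, oracle$p_value, tolerance = 1e-12)
})

test_that("perfect fit gives statistic 0 and p = 1", {
  r <- chi_square_vs_standard(two_cell_observed(50, 50),
                              two_cell_standard(500, 500))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)
})

test_that("the statistic only depends on the standard's proportions", {
  a <- chi_square_vs_standard(two_cell_observed(60, 40),
                              two_cell_standard(50, 50))
  b <- chi_square_vs_standard(two_cell_observed(60, 40),
                              two_cell_standard(5000, 5000))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("cells with small expected counts are pooled before testing", {
  obs <- tibble::tibble(
    age_band = factor(c("20-24", "25-29", "30-34"),
                      levels = age_band_levels(), ordered = TRUE),
    sex = "male", n = c(10, 9, 1))
  std <- as_standard_population(tibble::tibble(
    age_band = c("20-24", "25-29", "30-34"), sex = "male",
    count = c(10, 9, 1)))  # expected (10, 9, 1): last cell pools backwards
  r <- chi_square_vs_standard(obs, std)
  expect_equal(r$n_pooled, 1)
  expect_equal(r$df, 1)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
})

test_that("mean and median age follow the stated conventions", {
  one <- mean_median_age(make_cohort(38, "female"))
  expect_equal(one$mean_age[one$sex == "overall"], 38)
  expect_equal(one$median_age[one$sex == "overall"], 38)
  two <- mean_median_age(make_cohort(c(30, 40), c("male", "male")))
  expect_equal(two$mean_age[two$sex == "overall"], 35)
  expect_equal(two$median_age[two$sex == "overall"], 35)  # midpoint convention
  s <- small_synth(n = 1000, seed = 17)
  cohort <- complete_case_cohort(s$extract)
  mm <- mean_median_age(cohort)
  expect_equal(mm$mean_age[mm$sex == "overall"], mean(cohort$index_age))
  expect_equal(mm$median_age[mm$sex == "overall"],
               median(sort(cohort$index_age)))
})

case_set_for <- function(cohort, case_ids, condition = "test") {
  structure(
    tibble::tibble(patient_id = cohort$patient_id,
                   is_case = cohort$patient_id %in% case_ids,
                   onset_date = dplyr::if_else(
                     cohort$patient_id %in% case_ids, D("2006-06-01"),
                     as.Date(NA))),
    class = c("case_set", "tbl_df", "tbl", "data.frame"),
    condition_id = condition)
}

test_that("standardization reproduces the weighted-sum closed form", {
  # two female strata, rates 10% and 20%, standard weights 0.3/0.7 -> 17.0%
  cohort <- make_cohort(c(rep(2, 100), rep(7, 100)), rep("female", 200))
  cases <- case_set_for(cohort, cohort$patient_id[c(1:10, 101:120)])
  std <- as_standard_population(tibble::tibble(
    age_band = c("0-4", "5-9"), sex = "female", count = c(30, 70)))
  r <- standardized_prevalence(cases, cohort, std)
  expect_equal(r$standardized_pct, 17.0, tolerance = 1e-12)
  expect_equal(r$crude_pct, 15.0, tolerance = 1e-12)
  expect_equal(r$standardized_pct,
               bf_standardized_prevalence(cohort$patient_id[c(1:10, 101:120)],
                                          cohort, std),
               tolerance = 1e-12)
})

test_that("homogeneous stratum rates standardize to the common rate", {
  cohort <- make_cohort(c(rep(2, 50), rep(30, 50)),
                        rep(c("female", "male"), 50))
  # exactly 20% in every stratum
  ids <- unlist(lapply(split(cohort$patient_id,
                             paste(cohort$band, cohort$sex)),
                       function(x) head(x, length(x) / 5)))
  cases <- case_set_for(cohort, ids)
  r <- standardized_prevalence(cases, cohort, standard_population())
  expect_equal(r$standardized_pct, 20, tolerance = 1e-12)
  expect_equal(r$crude_pct, r$standardized_pct, tolerance = 1e-12)
})

test_that("crude equals standardized when the cohort mirrors the standard", {
  std <- as_standard_population(tibble::tibble(
    age_band = c("10-14", "40-44"), sex = "female", count = c(40, 60)))
  cohort <- make_cohort(c(rep(12, 40), rep(42, 60)), rep("female", 100))
  cases <- case_set_for(cohort, cohort$patient_id[c(1:4, 41:70)])
  r <- standardized_prevalence(cases, cohort, std)
  expect_equal(r$crude_pct, r$standardized_pct, tolerance = 1e-12)
})

test_that("zero cases give zero rates and a zero lower bound", {
  cohort <- make_cohort(rep(30, 20), rep("male", 20))
  cases <- case_set_for(cohort, character())
  r <- standardized_prevalence(cases, cohort, standard_population())
  expect_equal(r$crude_pct, 0)
  expect_equal(r$standardized_pct, 0)
  expect_equal(r$ci_low, 0)
  expect_gt(r$ci_high, 0)
})

test_that("standardized prevalence is bounded by the stratum rates and CI", {
  s <- small_synth(n = 800, seed = 23)
  cohort <- complete_case_cohort(s$extract)
  cs <- identify_cases(s$extract,
                       default_case_definitions()$definitions$hypertension,
                       cohort)
  r <- standardized_prevalence(cs, cohort, standard_population())
  rates <- cohort |>
    dplyr::left_join(cs, by = "patient_id") |>
    dplyr::group_by(band, sex) |>
    dplyr::summarise(rate = 100 * mean(is_case), .groups = "drop")
  expect_gte(r$standardized_pct, min(rates$rate) - 1e-9)
  expect_lte(r$standardized_pct, max(rates$rate) + 1e-9)
  expect_lte(r$ci_low, r$standardized_pct)
  expect_gte(r$ci_high, r$standardized_pct)
  # oracle agreement on the same fixture
  expect_equal(r$standardized_pct,
               bf_standardized_prevalence(cs$patient_id[cs$is_case], cohort,
                                          standard_population()),
               tolerance = 1e-12)
})
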