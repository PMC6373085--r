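test_that("sensitivity is the overlap over the gold standard", {
  ids <- sprintf("p%02d", 1:12)
  gold <- case_set_of(ids, sprintf("p%02d", 1:10))
  billing <- sprintf("p%02d", c(1:8, 11, 12))
  r <- sensitivity_vs_billing(gold, billing)
  expect_equal(r$value_pct, 80)
  expect_equal(r$n_gold, 10); expect_equal(r$n_billing, 10)
  expect_equal(r$n_overlap, 8)
  # identity: billing containing all of gold gives 100%
  r2 <- sensitivity_vs_billing(gold, c(sprintf("p%02d", 1:10), "x", "y"))
  expect_equal(r2$value_pct, 100)
  # removing billed patients never increases sensitivity
  r3 <- sensitivity_vs_billing(gold, sprintf("p%02d", 1:4))
  expect_lte(r3$value_pct, r$value_pct)
})

test_that("an empty gold standard is undefined, not zero", {
  gold <- case_set_of(sprintf("p%02d", 1:5), character())
  r <- sensitivity_vs_billing(gold, "p01")
  expect_true(r$undefined)
  expect_true(is.na(r$value_pct))
})

test_that("consistency of capture counts entries, markers and recent visitors", {
  ex <- make_mini_extract()
  cohort <- complete_case_cohort(ex)
  cc <- consistency_of_capture(ex, cohort)
  # problem list: m01, m02, m04, m06 of 8
  expect_equal(cc$value_pct[cc$measure == "problem_list"], 50)
  # allergies: m01, m03, m05 - the no-known-allergies marker counts
  expect_equal(cc$value_pct[cc$measure == "allergy_record"], 37.5)
  # final-year visitors: m01, m03, m05, m07 (2010 visits); of those m05 has meds
  expect_equal(cc$denominator[cc$measure == "medications"], 4L)
  expect_equal(cc$value_pct[cc$measure == "medications"], 25)
})

test_that("no recent visitors makes the medication measure undefined", {
  pts <- tibble::tibble(patient_id = "a", sex = "male",
                        birth_date = D("1980-01-01"))
  visits <- tibble::tibble(patient_id = "a", visit_date = D("2007-01-01"))
  ex <- emr_extract(patients = pts, visits = visits,
                    window_start = D("2006-01-01"),
                    window_end = D("2010-12-31"))
  cc <- consistency_of_capture(ex, complete_case_cohort(ex))
  med <- cc[cc$measure == "medications", ]
  expect_true(med$undefined)
  expect_true(is.na(med$value_pct))
})

test_that("vitals recording uses the right denominators and chi-squares", {
  # 200 adults, 100 per sex; 40 males and 60 females have a BP pair
  n <- 200
  pts <- tibble::tibble(
    patient_id = sprintf("p%03d", 1:n),
    sex = rep(c("male", "female"), each = 100),
    birth_date = D("1970-01-01"))
  rec <- c(sprintf("p%03d", 1:40), sprintf("p%03d", 101:160))
  vit <- tibble::tibble(
    patient_id = rep(rec, each = 2),
    measure_date = D("2008-01-01"),
    kind = rep(c("systolic_bp", "diastolic_bp"), 100),
    value = rep(c(120, 80), 100), units = "mmHg")
  ex <- emr_extract(patients = pts, vitals = vit,
                    window_start = D("2006-01-01"),
                    window_end = D("2010-12-31"))
  cohort <- complete_case_cohort(ex)
  r <- vitals_recording(ex, cohort, "bp")
  expect_equal(r$value_pct, 50)
  expect_equal(r$stat_sex, 8.0, tolerance = 1e-12)
  expect_equal(r$df_sex, 1L)
  oracle <- bf_chisq_indep(matrix(c(60, 40, 40, 60), 2))
  expect_equal(r$stat_sex, oracle$statistic, tolerance = 1e-12)
  expect_equal(r$p_sex, oracle$p_value, tolerance = 1e-12)
})

test_that("minors are excluded from the blood-pressure denominator entirely", {
  pts <- tibble::tibble(
    patient_id = c("kid", "adult"), sex = "female",
    birth_date = D(c("1989-06-01", "1970-01-01")))  # 16 and 36 at index
  vit <- tibble::tibble(
    patient_id = "kid", measure_date = D("2008-01-01"),
    kind = c("systolic_bp", "diastolic_bp"), value = c(110, 70),
    units = "mmHg")
  ex <- emr_extract(patients = pts, vitals = vit,
                    window_start = D("2006-01-01"),
                    window_end = D("2010-12-31"))
  r <- vitals_recording(ex, complete_case_cohort(ex), "bp")
  expect_equal(r$denominator, 1L)  # the adult only
  expect_equal(r$numerator, 0L)    # the kid's recording does not count
})

test_that("an empty vitals table gives zero percent, not undefined", {
  pts <- tibble::tibble(patient_id = "a", sex = "male",
                        birth_date = D("1970-01-01"))
  ex <- emr_extract(patients = pts,
                    vitals = tibble::tibble(patient_id = character(),
                                            measure_date = as.Date(character()),
                                            kind = character(),
                                            value = numeric(),
                                            units = character()),
                    window_start = D("2006-01-01"),
                    window_end = D("2010-12-31"))
  r <- vitals_recording(ex, complete_case_cohort(ex), "bp")
  expect_equal(r$value_pct, 0)
  expect_false(r$undefined)
})

test_that("single-component blood pressures count only in lenient mode", {
  pts <- tibble::tibble(patient_id = "a", sex = "male",
                        birth_date = D("1970-01-01"))
  vit <- tibble::tibble(patient_id = "a", measure_date = D("2008-01-01"),
                        kind = "systolic_bp", value = 130, units = "mmHg")
  ex <- emr_extract(patients = pts, vitals = vit,
                    window_start = D("2006-01-01"),
                    window_end = D("2010-12-31"))
  cohort <- complete_case_cohort(ex)
  expect_equal(vitals_recording(ex, cohort, "bp")$value_pct, 0)
  expect_equal(vitals_recording(ex, cohort, "bp", lenient_bp = TRUE)$value_pct,
               100)
})

test_that("the monitoring window after onset is closed at both stated edges", {
  make_ex <- function(bp_date) {
    pts <- tibble::tibble(patient_id = "a", sex = "male",
                          birth_date = D("1960-01-01"))
    vit <- tibble::tibble(patient_id = "a", measure_date = bp_date,
                          kind = c("systolic_bp", "diastolic_bp"),
                          value = c(120, 80), units = "mmHg")
    emr_extract(patients = pts, vitals = vit,
                window_start = D("2006-01-01"), window_end = D("2010-12-31"))
  }
  gold <- case_set_of("a", "a", onset = D("2007-01-01"),
                      condition = "diabetes")
  no_ht <- tibble::tibble(patient_id = character(),
                          onset_date = as.Date(character()))
  on_onset <- bp_among_requiring(make_ex(D("2007-01-01")), gold, no_ht)
  expect_equal(on_onset$value_pct[on_onset$condition_id == "diabetes"], 100)
  at_edge <- bp_among_requiring(make_ex(D("2007-01-01") + 365), gold, no_ht)
  expect_equal(at_edge$value_pct[at_edge$condition_id == "diabetes"], 100)
  past_edge <- bp_among_requiring(make_ex(D("2007-01-01") + 366), gold, no_ht)
  expect_equal(past_edge$value_pct[past_edge$condition_id == "diabetes"], 0)
  # empty hypertension-medication group is undefined
  expect_true(on_onset$undefined[on_onset$condition_id == "hypertension_meds"])
})

test_that("follow-up after onset is recovered from the generator's ledger", {
  s <- small_synth(n = 4000, seed = 29)
  cohort <- complete_case_cohort(s$extract)
  defs <- default_case_definitions()
  diab <- identify_cases(s$extract, defs$definitions$diabetes, cohort)
  ht_med <- hypertension_medication_patients(s$extract, cohort)
  ht_cs <- identify_cases(s$extract, defs$definitions$hypertension, cohort)
  ht_onset <- dplyr::inner_join(
    ht_med, dplyr::select(ht_cs, patient_id, onset_date), by = "patient_id")
  r <- bp_among_requiring(s$extract, diab,
                          ht_onset[, c("patient_id", "onset_date")])
  for (i in 1:2) {
    p <- r$value_pct[i] / 100
    se <- sqrt(0.9 * 0.1 / r$denominator[i])
    expect_lt(abs(p - 0.9), 3 * se)
  }
})
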