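defs <- default_case_definitions()

one_patient_extract <- function(..., birth = "1970-01-01", sex = "male") {
  emr_extract(
    patients = tibble::tibble(patient_id = "p", sex = sex,
                              birth_date = D(birth)),
    ...,
    window_start = D("2006-01-01"), window_end = D("2010-12-31"))
}

test_that("a single elevated HbA1c makes a diabetes case with lab-date onset", {
  ex <- one_patient_extract(
    labs = tibble::tibble(patient_id = "p", result_date = D("2008-03-01"),
                          test_code = "hba1c", value = 7.2, units = "%",
                          qualitative = NA_character_))
  r <- evaluate_case(ex, defs$definitions$diabetes, "p")
  expect_true(r$is_case)
  expect_equal(r$onset_date, D("2008-03-01"))
  # below threshold: not a case
  ex2 <- one_patient_extract(
    labs = tibble::tibble(patient_id = "p", result_date = D("2008-03-01"),
                          test_code = "hba1c", value = 6.4, units = "%",
                          qualitative = NA_character_))
  expect_false(evaluate_case(ex2, defs$definitions$diabetes, "p")$is_case)
})

test_that("a patient with no records is a case for no condition", {
  ex <- one_patient_extract()
  for (d in defs$definitions) {
    expect_false(evaluate_case(ex, d, "p")$is_case, label = d$condition_id)
  }
})

test_that("same-day height and weight derive BMI for the obesity rule", {
  v <- tibble::tibble(
    patient_id = "p", measure_date = D("2009-06-01"),
    kind = c("height", "weight"), value = c(160, 80), units = c("cm", "kg"))
  ex <- one_patient_extract(vitals = v)
  r <- evaluate_case(ex, defs$definitions$obesity, "p")
  expect_true(r$is_case)  # BMI = 80 / 1.60^2 = 31.25
  expect_equal(r$onset_date, D("2009-06-01"))
  # same pair but on different days: no derivable BMI
  v2 <- v; v2$measure_date <- D(c("2009-06-01", "2009-06-02"))
  expect_false(evaluate_case(one_patient_extract(vitals = v2),
                             defs$definitions$obesity, "p")$is_case)
  # BMI below 30 is not obese
  v3 <- v; v3$value <- c(180, 80)
  expect_false(evaluate_case(one_patient_extract(vitals = v3),
                             defs$definitions$obesity, "p")$is_case)
})

test_that("the asthma definition is restricted to patients under 18", {
  problems <- tibble::tibble(patient_id = "p", entry_date = D("2008-01-01"),
                             text = "asthma", code = NA_character_)
  adult <- one_patient_extract(problems = problems, birth = "1966-01-01")
  expect_false(evaluate_case(adult, defs$definitions$asthma, "p")$is_case)
  child <- one_patient_extract(problems = problems, birth = "1996-01-02")
  expect_true(evaluate_case(child, defs$definitions$asthma, "p")$is_case)
})

test_that("hypertension medication rule needs two distinct drugs or a diuretic", {
  two <- tibble::tibble(
    patient_id = "p", start_date = D(c("2007-01-01", "2007-06-01")),
    name = c("ramipril", "amlodipine"), class_code = NA_character_)
  r <- evaluate_case(one_patient_extract(medications = two),
                     defs$definitions$hypertension, "p")
  expect_true(r$is_case)
  # onset: the date the second distinct drug appears
  expect_equal(r$onset_date, D("2007-06-01"))

  one_drug_twice <- two; one_drug_twice$name <- c("ramipril", "Ramipril 5 mg")
  expect_false(evaluate_case(one_patient_extract(medications = one_drug_twice),
                             defs$definitions$hypertension, "p")$is_case)

  diuretic <- tibble::tibble(patient_id = "p", start_date = D("2007-01-01"),
                             name = "hydrochlorothiazide",
                             class_code = NA_character_)
  expect_true(evaluate_case(one_patient_extract(medications = diuretic),
                            defs$definitions$hypertension, "p")$is_case)
})

test_that("two high blood-pressure readings on distinct dates qualify", {
  v <- tibble::tibble(
    patient_id = "p",
    measure_date = D(rep(c("2007-01-01", "2008-01-01"), each = 2)),
    kind = rep(c("systolic_bp", "diastolic_bp"), 2),
    value = c(150, 85, 145, 88), units = "mmHg")
  r <- evaluate_case(one_patient_extract(vitals = v),
                     defs$definitions$hypertension, "p")
  expect_true(r$is_case)
  expect_equal(r$onset_date, D("2008-01-01"))
  # a single high date is not enough
  v1 <- v[v$measure_date == D("2007-01-01"), ]
  expect_false(evaluate_case(one_patient_extract(vitals = v1),
                             defs$definitions$hypertension, "p")$is_case)
  # two normal readings are not high
  v$value <- c(120, 70, 118, 72)
  expect_false(evaluate_case(one_patient_extract(vitals = v),
                             defs$definitions$hypertension, "p")$is_case)
})

test_that("UTI needs a positive culture with an antibiotic within 14 days", {
  labs <- tibble::tibble(patient_id = "p", result_date = D("2009-01-01"),
                         test_code = "urine_culture", value = NA_real_,
                         units = NA_character_, qualitative = "positive")
  med_ok <- tibble::tibble(patient_id = "p", start_date = D("2009-01-15"),
                           name = "nitrofurantoin", class_code = NA_character_)
  r <- evaluate_case(one_patient_extract(labs = labs, medications = med_ok),
                     defs$definitions$urinary_tract_infection, "p")
  expect_true(r$is_case)
  med_late <- med_ok; med_late$start_date <- D("2009-01-16")
  expect_false(evaluate_case(
    one_patient_extract(labs = labs, medications = med_late),
    defs$definitions$urinary_tract_infection, "p")$is_case)
})

test_that("definitions without clauses or with bad lab atoms are rejected", {
  expect_error(case_definition("x", list()), "at least one clause")
  expect_error(case_definition("x", list(list(lab = list(test = "t")))),
               "needs `op`")
})

test_that("unit mismatches between definition and extract are errors", {
  labs <- tibble::tibble(patient_id = "p", result_date = D("2008-03-01"),
                         test_code = "hba1c", value = 55,
                         units = "mmol/mol", qualitative = NA_character_)
  ex <- one_patient_extract(labs = labs)
  expect_error(evaluate_case(ex, defs$definitions$diabetes, "p"),
               "Unit mismatch")
})

test_that("adding records never unmakes a case nor delays onset", {
  s <- small_synth(n = 150, seed = 21)
  cohort <- complete_case_cohort(s$extract)
  for (cid in c("diabetes", "hypertension", "obesity")) {
    before <- identify_cases(s$extract, defs$definitions[[cid]], cohort)
    aug <- s$extract
    extra <- tibble::tibble(
      patient_id = cohort$patient_id,
      entry_date = D("2006-02-01"),
      text = "unrelated note", code = NA_character_)
    aug$problems <- dplyr::bind_rows(aug$problems, extra)
    after <- identify_cases(aug, defs$definitions[[cid]], cohort)
    expect_true(all(after$is_case[before$is_case]), label = cid)
    both <- before$is_case & after$is_case
    expect_true(all(after$onset_date[both] <= before$onset_date[both]),
                label = cid)
  }
})

test_that("identify_cases equals per-patient evaluation and the loop oracle", {
  s <- small_synth(n = 100, seed = 31)
  cohort <- complete_case_cohort(s$extract)
  for (cid in names(defs$definitions)) {
    cs <- identify_cases(s$extract, defs$definitions[[cid]], cohort)
    for (i in seq_len(nrow(cohort))) {
      pid <- cohort$patient_id[i]
      ev <- evaluate_case(s$extract, defs$definitions[[cid]], pid)
      expect_equal(cs$is_case[cs$patient_id == pid], ev$is_case,
                   label = paste(cid, pid))
      oracle <- bf_is_case(s$extract, cid, pid, cohort$index_age[i])
      expect_equal(cs$is_case[cs$patient_id == pid], oracle,
                   label = paste("oracle", cid, pid))
    }
  }
})

test_that("billing positives match codes exactly after trimming", {
  ex <- make_mini_extract()
  cohort <- complete_case_cohort(ex)
  expect_equal(billing_positives(ex, "diabetes", cohort = cohort), "m01")
  expect_equal(billing_positives(ex, "hypertension", cohort = cohort), "m02")
  expect_equal(billing_positives(ex, "obesity", cohort = cohort), character())
  no_billing <- emr_extract(
    patients = ex$patients,
    window_start = ex$window_start, window_end = ex$window_end)
  expect_equal(billing_positives(no_billing, "diabetes", cohort = cohort),
               character())
})
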