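# Hand-built fixtures and a minimal cohort constructor used across tests.

D <- function(x) as.Date(x)

make_cohort <- function(ages, sexes, ids = sprintf("c%03d", seq_along(ages)),
                        index_date = as.Date("2006-01-01")) {
  ages <- as.integer(ages)
  cohort <- tibble::tibble(
    patient_id = ids, sex = sexes,
    birth_date = as.Date(sprintf("%d-01-01", 2006 - ages)) - 1,
    index_age = ages,
    band = age_band(ages)
  )
  structure(cohort, class = c("emr_cohort", class(cohort)),
            index_date = index_date,
            exclusions = tibble::tibble(reason = character(), n = integer()))
}

# A small hand-built extract exercising every record table. Window 2006-2010.
make_mini_extract <- function() {
  patients <- tibble::tibble(
    patient_id = sprintf("m%02d", 1:8),
    sex = c("female", "male", "female", "male", "female", "male", "female", "male"),
    birth_date = D(c("1970-06-01", "1950-03-15", "1996-09-30", "2000-02-10",
                     "1980-12-25", "1940-07-04", "1988-05-05", "1930-01-01"))
  )
  visits <- tibble::tibble(
    patient_id = c("m01", "m01", "m02", "m03", "m04", "m05", "m06", "m07", "m08"),
    visit_date = D(c("2008-01-02", "2010-03-04", "2009-06-01", "2010-05-05",
                     "2009-09-09", "2010-11-30", "2007-01-15", "2010-10-10",
                     "2006-02-02"))
  )
  problems <- tibble::tibble(
    patient_id = c("m01", "m02", "m04", "m06"),
    entry_date = D(c("2007-05-01", "2006-08-01", "2008-03-01", "2006-06-15")),
    text = c("Type II Diabetes Mellitus", "HTN", "asthma", "hypothyroid"),
    code = NA_character_
  )
  medications <- tibble::tibble(
    patient_id = c("m02", "m02", "m05", "m06"),
    start_date = D(c("2006-09-01", "2007-02-01", "2010-04-01", "2006-07-01")),
    name = c("ramipril", "amlodipine", "nitrofurantoin", "levothyroxine"),
    class_code = c("oral_antihypertensive", "oral_antihypertensive",
                   "antibiotic", "thyroid_replacement")
  )
  labs <- tibble::tibble(
    patient_id = c("m01", "m03", "m05", "m07"),
    result_date = D(c("2007-05-01", "2009-01-20", "2010-03-25", "2010-09-01")),
    test_code = c("hba1c", "glucose_fasting", "urine_culture", "pregnancy_hcg"),
    value = c(7.2, 5.1, NA, NA),
    units = c("%", "mmol/L", NA, NA),
    qualitative = c(NA, NA, "positive", "positive")
  )
  vitals <- tibble::tibble(
    patient_id = c("m01", "m01", "m02", "m02", "m05", "m05", "m08"),
    measure_date = D(c("2010-03-04", "2010-03-04", "2009-06-01", "2009-06-01",
                       "2010-11-30", "2010-11-30", "2006-02-02")),
    kind = c("systolic_bp", "diastolic_bp", "systolic_bp", "diastolic_bp",
             "height", "weight", "weight"),
    value = c(128, 82, 150, 95, 160, 80, 70),
    units = c("mmHg", "mmHg", "mmHg", "mmHg", "cm", "kg", "kg")
  )
  billing <- tibble::tibble(
    patient_id = c("m01", "m02", "m03"),
    service_date = D(c("2008-01-02", "2009-06-01", "2010-05-05")),
    diag_code = c("250 ", "401", "493")
  )
  immunizations <- tibble::tibble(
    patient_id = "m04",
    given_date = D("2006-04-01"),
    vaccine = "DTaP-IPV-Hib"
  )
  allergies <- tibble::tibble(
    patient_id = c("m01", "m03", "m05"),
    recorded_date = D(c("2006-03-01", "2009-02-01", "2010-01-01")),
    substance = c("penicillin", no_known_allergies(), "latex")
  )
  emr_extract(patients = patients, visits = visits, problems = problems,
              medications = medications, labs = labs, vitals = vitals,
              billing = billing, immunizations = immunizations,
              allergies = allergies,
              window_start = D("2006-01-01"), window_end = D("2010-12-31"))
}

small_synth <- function(n = 400, seed = 11, ...) {
  suppressMessages(synth_emr(synth_config(n_patients = n, seed = seed, ...)))
}

case_set_of <- function(ids, case_ids, onset = D("2007-01-01"),
                        condition = "test") {
  structure(
    tibble::tibble(patient_id = ids, is_case = ids %in% case_ids,
                   onset_date = dplyr::if_else(ids %in% case_ids, onset,
                                               as.Date(NA))),
    class = c("case_set", "tbl_df", "tbl", "data.frame"),
    condition_id = condition)
}
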