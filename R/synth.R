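# Synthetic EMR generation. The generator emulates the statistical structure
# the quality measures consume: an age-sex roster drawn from a standard
# population, six conditions with configured prevalence, billing concordance
# as two coin flips (case -> billed with sensitivity, non-case -> billed with
# a false-billing rate), record-type presence at configured recording rates,
# and timeliness flags that place vitals inside or outside the one-year
# window before the last visit. Every truth is written to a ledger so the
# pipeline's measures can be checked against known parameters.

synth_condition_defaults <- function() {
  tibble::tribble(
    ~condition_id,             ~prevalence, ~billing_sensitivity, ~billing_false_rate,
    "diabetes",                0.068,       0.80,                 0.02,
    "hypertension",            0.191,       0.65,                 0.05,
    "hypothyroidism",          0.071,       0.50,                 0.01,
    "asthma",                  0.211,       0.40,                 0.01,
    "obesity",                 0.241,       0.15,                 0.01,
    "urinary_tract_infection", 0.030,       0.65,                 0.02
  )
}

#' Configuration for the synthetic EMR generator
#'
#' Defaults describe a mid-sized primary care network over a five-year
#' window; prevalences default to published population figures for the six
#' test conditions (asthma applies to patients under 18) and
#' recording/timeliness rates to the mid-range of values reported for
#' EMR-derived datasets. All rates are fractions in `[0, 1]`.
#'
#' @param n_patients Roster size (default 2500).
#' @param seed Integer seed; a fixed seed makes [synth_emr()] byte-identical.
#' @param window_start,window_end Observation window.
#' @param age_sex A `standard_population` supplying age-sex sampling weights
#'   (default: the bundled [standard_population()]).
#' @param conditions Tibble `condition_id`, `prevalence`,
#'   `billing_sensitivity`, `billing_false_rate`.
#' @param recording Named fractions: probability a patient has any
#'   `problem_list`, `allergy`, `medication`, `bp`, `height`, `weight`
#'   records.
#' @param timeliness Named fractions (`bp`, `height`, `weight`): probability
#'   a patient's vitals fall within one year before their last visit.
#' @param bp_onset_followup Probability a patient requiring blood-pressure
#'   monitoring (diabetes, hypertension medications) has a reading within 12
#'   months of onset.
#' @param pregnancy_rate Probability a woman aged 15-45 has a positive
#'   pregnancy test in the window.
#' @param pregnancy_followup Probability of a visit within 62 days after a
#'   positive pregnancy test.
#' @param tetanus_misrecord Probability a patient aged 10+ carries a
#'   misrecorded tetanus conjugate vaccination (default 0).
#' @param missing_sex,missing_age Probability of a missing sex / birth date
#'   on the roster.
#' @param dialect `"structured"` (coded problem list and medication classes)
#'   or `"free_text"` (synonym/dosage variants, no codes).
#' @param visits_mean Mean extra visits per patient (each patient has at
#'   least one).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 2500, seed = 1L,
                         window_start = as.Date("2006-01-01"),
                         window_end = as.Date("2010-12-31"),
                         age_sex = NULL,
                         conditions = synth_condition_defaults(),
                         recording = c(problem_list = 0.70, allergy = 0.48,
                                       medication = 0.70, bp = 0.87,
                                       height = 0.55, weight = 0.70),
                         timeliness = c(bp = 0.75, height = 0.40, weight = 0.55),
                         bp_onset_followup = 0.90,
                         pregnancy_rate = 0.05, pregnancy_followup = 0.50,
                         tetanus_misrecord = 0,
                         missing_sex = 0.002, missing_age = 0.004,
                         dialect = c("structured", "free_text"),
                         visits_mean = 5) {
  dialect <- match.arg(dialect)
  if (n_patients <= 0) abort("`n_patients` must be positive.")
  fracs <- c(conditions$prevalence, conditions$billing_sensitivity,
             conditions$billing_false_rate, recording, timeliness,
             bp_onset_followup, pregnancy_rate, pregnancy_followup,
             tetanus_misrecord, missing_sex, missing_age)
  if (any(fracs < 0 | fracs > 1)) {
    abort("All configured rates must be fractions in [0, 1].")
  }
  needed <- c("problem_list", "allergy", "medication", "bp", "height", "weight")
  if (!all(needed %in% names(recording))) {
    abort(sprintf("`recording` must name: %s.", paste(needed, collapse = ", ")))
  }
  if (!all(c("bp", "height", "weight") %in% names(timeliness))) {
    abort("`timeliness` must name bp, height and weight.")
  }
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         window_start = as.Date(window_start), window_end = as.Date(window_end),
         age_sex = age_sex, conditions = conditions, recording = recording,
         timeliness = timeliness, bp_onset_followup = bp_onset_followup,
         pregnancy_rate = pregnancy_rate, pregnancy_followup = pregnancy_followup,
         tetanus_misrecord = tetanus_misrecord, missing_sex = missing_sex,
         missing_age = missing_age, dialect = dialect,
         visits_mean = visits_mean),
    class = "synth_config")
}

# Integer uniform on [a, b], vectorized over a/b.
runi <- function(n, a, b) a + floor(stats::runif(n) * (b - a + 1))

# Presence coin with a forced subset: members of `forced` always have the
# record type; the rest draw a coin adjusted so the marginal rate over
# `population` equals `p` exactly in expectation.
forced_coin <- function(population_n, forced, p) {
  m <- sum(forced)
  q <- if (population_n - m <= 0) 0 else (p * population_n - m) / (population_n - m)
  if (q < 0) {
    warn(paste("Configured recording rate is below the fraction of patients",
               "whose case status requires the record type; using the",
               "attainable minimum."))
    q <- 0
  }
  forced | (stats::runif(population_n) < q)
}

# Sample one day uniformly from [lo, hi] minus [a_lo, a_hi]; scalar. Keeps
# `fallback` when the allowed set is empty (a measure-zero configuration).
sample_day_avoid <- function(lo, hi, a_lo, a_hi, fallback) {
  days <- seq.int(lo, hi)
  days <- days[days < a_lo | days > a_hi]
  if (length(days) == 0) return(fallback)
  days[runi(1, 1, length(days))]
}

free_text_problem <- function(token, n, dictionary) {
  variants <- dictionary$variant[dictionary$token == token]
  v <- variants[runi(n, 1, length(variants))]
  # randomized capitalization/punctuation, undone by normalization
  decorate <- runi(n, 1, 3)
  out <- ifelse(decorate == 1, toupper(v),
                ifelse(decorate == 2, stringr::str_to_title(v), v))
  ifelse(runi(n, 0, 1) == 1, paste0(out, "."), out)
}

benign_problems <- c("routine examination", "low back pain", "migraine",
                     "anxiety", "gerd", "knee osteoarthritis",
                     "seasonal rhinitis")
benign_meds <- c("multivitamin", "acetaminophen", "ibuprofen", "omeprazole",
                 "atorvastatin", "cetirizine")
oral_antihypertensives <- c("amlodipine", "ramipril", "lisinopril",
                            "candesartan", "metoprolol")
diuretics <- c("hydrochlorothiazide", "indapamide")
allergy_substances <- c("penicillin", "peanuts", "sulfa", "latex", "shellfish")

med_row <- function(ids, dates, names, class_codes, dialect) {
  nm <- if (dialect == "free_text") {
    paste0(stringr::str_to_title(names), " ", runi(length(names), 1, 8) * 125, " mg")
  } else names
  tibble(patient_id = ids, start_date = dates, name = nm,
         class_code = if (dialect == "free_text") NA_character_ else class_codes)
}

#' Generate a synthetic EMR extract with a ground-truth ledger
#'
#' Draws a patient roster from the configured age-sex structure, assigns true
#' conditions, and writes records so that (with no degradation) the shipped
#' default case definitions recover the ledger exactly while every configured
#' recording, timeliness, concordance and follow-up rate equals the expected
#' value of the corresponding pipeline measure. Patients whose case status
#' requires a record type (problem list for any case; blood pressure for
#' patients needing monitoring; weight for obesity) always carry it, and the
#' remaining patients' presence probability is adjusted so the marginal rate
#' matches the knob.
#'
#' @param config A [synth_config()].
#' @return List of class `synth_emr`: `extract` (a validated
#'   [emr_extract()]) and `ground_truth` (one row per patient: true
#'   demographics, per-condition case status and onset, billing flags, and
#'   every presence/timeliness/follow-up flag used during generation).
#' @export
synth_emr <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::local_seed(config$seed)

  n <- config$n_patients
  ws <- as.integer(config$window_start)
  we <- as.integer(config$window_end)
  W <- we - ws
  ids <- sprintf("p%06d", seq_len(n))
  dict <- term_dictionary()

  # --- roster -----------------------------------------------------------
  std <- config$age_sex %||% standard_population()
  cells <- std[std$count > 0, ]
  pick <- sample.int(nrow(cells), n, replace = TRUE, prob = cells$count)
  sex <- cells$sex[pick]
  band <- as.character(cells$age_band[pick])
  band_start <- as.integer(sub("[-+].*", "", band))
  top <- !grepl("-", band)
  age <- band_start + ifelse(top, runi(n, 0, 9), runi(n, 0, 4))
  birth <- as.integer(as.Date(sprintf("%d-01-01",
                                      lubridate::year(config$window_start) - age))) -
    runi(n, 0, 364)

  missing_sex <- stats::runif(n) < config$missing_sex
  missing_age <- stats::runif(n) < config$missing_age

  # --- visits -----------------------------------------------------------
  n_visits <- stats::rpois(n, config$visits_mean) + 1L
  visits <- tibble(
    patient_id = rep(ids, n_visits),
    visit_date = as.Date(runi(sum(n_visits), ws, we), origin = "1970-01-01")
  )
  lv <- as.integer(tapply(as.integer(visits$visit_date), visits$patient_id, max)[ids])

  # --- true conditions --------------------------------------------------
  conds <- config$conditions
  truth <- tibble(patient_id = ids, sex_true = sex, birth_true =
                    as.Date(birth, origin = "1970-01-01"), index_age = age,
                  missing_sex = missing_sex, missing_age = missing_age)
  is_case <- list(); onset <- list()
  for (i in seq_len(nrow(conds))) {
    cid <- conds$condition_id[i]
    eligible <- if (cid == "asthma") age < 18 else rep(TRUE, n)
    is_case[[cid]] <- eligible & stats::runif(n) < conds$prevalence[i]
    onset[[cid]] <- ifelse(is_case[[cid]], ws + runi(n, 0, floor(W / 2)), NA)
    truth[[paste0("case_", cid)]] <- is_case[[cid]]
    truth[[paste0("onset_", cid)]] <-
      as.Date(onset[[cid]], origin = "1970-01-01")
  }
  any_case <- Reduce(`|`, is_case)

  # --- record-type presence --------------------------------------------
  rec <- config$recording
  has_med <- stats::runif(n) < rec[["medication"]]
  ht_med_group <- is_case$hypertension & has_med
  needs_bp <- is_case$diabetes | ht_med_group
  adult <- age >= 18
  has_bp <- logical(n)
  has_bp[adult] <- forced_coin(sum(adult), needs_bp[adult], rec[["bp"]])
  has_bp[!adult] <- needs_bp[!adult] |
    (stats::runif(sum(!adult)) < rec[["bp"]])
  has_problem <- forced_coin(n, any_case, rec[["problem_list"]])
  has_weight <- forced_coin(n, is_case$obesity, rec[["weight"]])
  has_height <- stats::runif(n) < rec[["height"]]
  has_allergy <- stats::runif(n) < rec[["allergy"]]

  tl <- config$timeliness
  timely <- list(bp = stats::runif(n) < tl[["bp"]],
                 height = stats::runif(n) < tl[["height"]],
                 weight = stats::runif(n) < tl[["weight"]])
  fu_diab <- stats::runif(n) < config$bp_onset_followup
  fu_ht <- stats::runif(n) < config$bp_onset_followup

  truth$has_problem <- has_problem; truth$has_medication <- has_med
  truth$has_bp <- has_bp; truth$has_height <- has_height
  truth$has_weight <- has_weight; truth$has_allergy <- has_allergy
  truth$timely_bp <- timely$bp; truth$timely_height <- timely$height
  truth$timely_weight <- timely$weight
  truth$bp_followup_diabetes <- fu_diab & is_case$diabetes
  truth$bp_followup_hypertension <- fu_ht & ht_med_group
  truth$hypertension_med_group <- ht_med_group

  # --- vitals dates -----------------------------------------------------
  # Primary row anchored on the last visit: inside [lv-365, lv] when timely,
  # inside [lv-730, lv-366] otherwise (records may predate the window).
  primary_date <- function(has, tflag) {
    d <- ifelse(tflag, lv - runi(n, 0, 365), lv - runi(n, 366, 730))
    ifelse(has, d, NA)
  }
  d_bp <- primary_date(has_bp, timely$bp)
  d_h <- primary_date(has_height, timely$height)
  d_w <- primary_date(has_weight, timely$weight)

  # Keep non-followup monitored patients' readings out of the onset window.
  avoid_onset <- function(d, group, fu, on) {
    fix <- which(group & !fu & !is.na(d) & d >= on & d <= on + 365)
    for (i in fix) {
      rng <- if (timely$bp[i]) c(lv[i] - 365, lv[i]) else c(lv[i] - 730, lv[i] - 366)
      d[i] <- sample_day_avoid(rng[1], rng[2], on[i], on[i] + 365, d[i])
    }
    d
  }
  d_bp <- avoid_onset(d_bp, is_case$diabetes, fu_diab, onset$diabetes)
  d_bp <- avoid_onset(d_bp, ht_med_group, fu_ht, onset$hypertension)

  # Follow-up reading within 12 months of onset for monitored patients.
  followup_dates <- function(group, fu, on) {
    idx <- which(group & fu)
    d <- on[idx] + runi(length(idx), 0, 365)
    bad <- which(!timely$bp[idx] & d >= lv[idx] - 365 & d <= lv[idx])
    for (j in bad) {
      i <- idx[j]
      d[j] <- sample_day_avoid(on[i], on[i] + 365, lv[i] - 365, lv[i], d[j])
    }
    tibble(i = idx, date = d)
  }
  fu_rows <- bind_rows(
    followup_dates(is_case$diabetes, fu_diab, onset$diabetes),
    followup_dates(ht_med_group, fu_ht, onset$hypertension)
  )

  bp_values <- function(i) {
    ht <- is_case$hypertension[i]
    tibble(
      systolic = ifelse(ht, stats::runif(length(i), 145, 180),
                        stats::runif(length(i), 100, 135)),
      diastolic = ifelse(ht, stats::runif(length(i), 92, 110),
                         stats::runif(length(i), 62, 85))
    )
  }
  bp_idx <- c(which(has_bp), fu_rows$i)
  bp_dates <- c(d_bp[which(has_bp)], fu_rows$date)
  bpv <- bp_values(bp_idx)
  vitals_bp <- tibble(
    patient_id = rep(ids[bp_idx], 2),
    measure_date = as.Date(rep(bp_dates, 2), origin = "1970-01-01"),
    kind = rep(c("systolic_bp", "diastolic_bp"), each = length(bp_idx)),
    value = round(c(bpv$systolic, bpv$diastolic)),
    units = "mmHg"
  )

  height_m_lat <- ifelse(age < 18, stats::runif(n, 1.2, 1.8),
                         stats::runif(n, 1.50, 1.90))
  bmi_lat <- ifelse(is_case$obesity, stats::runif(n, 30.5, 45),
                    stats::runif(n, 18.5, 29))
  vitals_h <- tibble(patient_id = ids[has_height],
                     measure_date = as.Date(d_h[has_height], origin = "1970-01-01"),
                     kind = "height",
                     value = round(height_m_lat[has_height] * 100, 1),
                     units = "cm")
  vitals_w <- tibble(patient_id = ids[has_weight],
                     measure_date = as.Date(d_w[has_weight], origin = "1970-01-01"),
                     kind = "weight",
                     value = round(bmi_lat[has_weight] *
                                     height_m_lat[has_weight]^2, 1),
                     units = "kg")
  vitals <- bind_rows(vitals_bp, vitals_h, vitals_w)

  # --- problem list -----------------------------------------------------
  prob_rows <- list()
  for (cid in conds$condition_id) {
    idx <- which(is_case[[cid]] & has_problem)
    if (length(idx) == 0) next
    text <- if (config$dialect == "free_text") {
      free_text_problem(cid, length(idx), dict)
    } else rep(gsub("_", " ", cid), length(idx))
    prob_rows[[cid]] <- tibble(
      patient_id = ids[idx],
      entry_date = as.Date(onset[[cid]][idx], origin = "1970-01-01"),
      text = text,
      code = if (config$dialect == "structured") cid else NA_character_)
  }
  filler_idx <- which(has_problem & !any_case)
  prob_rows$filler <- tibble(
    patient_id = ids[filler_idx],
    entry_date = as.Date(runi(length(filler_idx), ws, we), origin = "1970-01-01"),
    text = benign_problems[runi(length(filler_idx), 1, length(benign_problems))],
    code = NA_character_)
  problems <- bind_rows(prob_rows)

  # --- medications ------------------------------------------------------
  med_rows <- list()
  dial <- config$dialect
  idx <- which(ht_med_group)
  if (length(idx) > 0) {
    use_diuretic <- stats::runif(length(idx)) < 0.3
    di <- idx[use_diuretic]; oa <- idx[!use_diuretic]
    med_rows$diuretic <- med_row(
      ids[di], as.Date(onset$hypertension[di] + runi(length(di), 0, 90),
                       origin = "1970-01-01"),
      diuretics[runi(length(di), 1, length(diuretics))], "diuretic", dial)
    pick2 <- t(vapply(seq_along(oa), function(i)
      sample.int(length(oral_antihypertensives), 2), integer(2)))
    med_rows$oa <- med_row(
      rep(ids[oa], 2),
      as.Date(rep(onset$hypertension[oa], 2) + runi(2 * length(oa), 0, 90),
              origin = "1970-01-01"),
      oral_antihypertensives[c(pick2[, 1], pick2[, 2])],
      "oral_antihypertensive", dial)
  }
  simple_med <- function(cid, drug, class_code, delay_max = 60) {
    idx <- which(is_case[[cid]] & has_med)
    med_row(ids[idx],
            as.Date(onset[[cid]][idx] + runi(length(idx), 0, delay_max),
                    origin = "1970-01-01"),
            rep(drug, length(idx)), class_code, dial)
  }
  med_rows$diabetes <- simple_med("diabetes", "metformin", "antihyperglycemic")
  med_rows$hypothyroidism <- simple_med("hypothyroidism", "levothyroxine",
                                        "thyroid_replacement")
  med_rows$asthma <- simple_med("asthma", "salbutamol", "asthma_inhaler")
  med_rows$uti <- simple_med("urinary_tract_infection", "nitrofurantoin",
                             "antibiotic", delay_max = 14)
  bidx <- which(has_med)
  med_rows$benign <- med_row(
    ids[bidx], as.Date(runi(length(bidx), ws, we), origin = "1970-01-01"),
    benign_meds[runi(length(bidx), 1, length(benign_meds))], NA_character_, dial)
  medications <- bind_rows(med_rows)

  # --- labs -------------------------------------------------------------
  lab_rows <- list()
  di <- which(is_case$diabetes)
  lab_rows$hba1c <- tibble(
    patient_id = ids[di],
    result_date = as.Date(onset$diabetes[di], origin = "1970-01-01"),
    test_code = "hba1c", value = round(stats::runif(length(di), 6.6, 9.5), 1),
    units = "%", qualitative = NA_character_)
  ui <- which(is_case$urinary_tract_infection)
  lab_rows$culture <- tibble(
    patient_id = ids[ui],
    result_date = as.Date(onset$urinary_tract_infection[ui], origin = "1970-01-01"),
    test_code = "urine_culture", value = NA_real_, units = NA_character_,
    qualitative = "positive")
  gi <- which(stats::runif(n) < 0.3)
  lab_rows$glucose <- tibble(
    patient_id = ids[gi],
    result_date = as.Date(runi(length(gi), ws, we), origin = "1970-01-01"),
    test_code = "glucose_fasting",
    value = round(stats::runif(length(gi), 4, 6.4), 1),
    units = "mmol/L", qualitative = NA_character_)

  # Pregnancy: positive tests for women 15-45, anchored on the visit
  # schedule so the follow-up fraction is exactly the configured rate.
  eligible_preg <- which(sex == "female" & age >= 15 & age <= 45)
  pregnant <- eligible_preg[stats::runif(length(eligible_preg)) <
                              config$pregnancy_rate]
  preg_fu <- stats::runif(length(pregnant)) < config$pregnancy_followup
  preg_date <- integer(length(pregnant))
  vis_by_pat <- split(as.integer(visits$visit_date), visits$patient_id)
  for (j in seq_along(pregnant)) {
    i <- pregnant[j]
    if (preg_fu[j]) {
      vv <- vis_by_pat[[ids[i]]]
      anchor <- vv[runi(1, 1, length(vv))]
      preg_date[j] <- anchor - runi(1, 1, 62)
    } else {
      preg_date[j] <- min(lv[i] + runi(1, 0, 30), we)
    }
  }
  lab_rows$pregnancy <- tibble(
    patient_id = ids[pregnant],
    result_date = as.Date(preg_date, origin = "1970-01-01"),
    test_code = "pregnancy_hcg", value = NA_real_, units = NA_character_,
    qualitative = "positive")
  neg <- setdiff(eligible_preg, pregnant)
  neg <- neg[stats::runif(length(neg)) < 0.05]
  lab_rows$pregnancy_neg <- tibble(
    patient_id = ids[neg],
    result_date = as.Date(runi(length(neg), ws, we), origin = "1970-01-01"),
    test_code = "pregnancy_hcg", value = NA_real_, units = NA_character_,
    qualitative = "negative")
  labs <- bind_rows(lab_rows)
  truth$pregnancy_positive <- seq_len(n) %in% pregnant
  truth$pregnancy_followup <- FALSE
  truth$pregnancy_followup[pregnant] <- preg_fu

  # --- allergies --------------------------------------------------------
  ai <- which(has_allergy)
  marker <- stats::runif(length(ai)) < 0.3
  allergies <- tibble(
    patient_id = ids[ai],
    recorded_date = as.Date(runi(length(ai), ws, we), origin = "1970-01-01"),
    substance = ifelse(marker, no_known_allergies(),
                       allergy_substances[runi(length(ai), 1,
                                               length(allergy_substances))]))

  # --- immunizations ----------------------------------------------------
  imm_rows <- list()
  age_end <- years_between(as.Date(birth, origin = "1970-01-01"),
                           config$window_end)
  kids <- which(age_end < 10 & stats::runif(n) < 0.8)
  kid_date <- pmin(birth[kids] + 60 + runi(length(kids), 0, 1400), we)
  imm_rows$routine <- tibble(
    patient_id = ids[kids],
    given_date = as.Date(kid_date, origin = "1970-01-01"),
    vaccine = "DTaP-IPV-Hib")
  flu <- which(stats::runif(n) < 0.2)
  imm_rows$flu <- tibble(
    patient_id = ids[flu],
    given_date = as.Date(runi(length(flu), ws, we), origin = "1970-01-01"),
    vaccine = "influenza")
  mis <- which(age_end >= 10 & stats::runif(n) < config$tetanus_misrecord)
  mis_lo <- pmax(birth[mis] + as.integer(round(10 * 365.25)), ws)
  imm_rows$misrecord <- tibble(
    patient_id = ids[mis],
    given_date = as.Date(runi(length(mis), mis_lo, we), origin = "1970-01-01"),
    vaccine = "tetanus toxoid conjugate (DTaP-IPV-Hib)")
  immunizations <- bind_rows(imm_rows)
  truth$tetanus_misrecorded <- seq_len(n) %in% mis

  # --- billing ----------------------------------------------------------
  defs <- default_case_definitions()
  bill_rows <- list()
  for (i in seq_len(nrow(conds))) {
    cid <- conds$condition_id[i]
    billed <- ifelse(is_case[[cid]],
                     stats::runif(n) < conds$billing_sensitivity[i],
                     stats::runif(n) < conds$billing_false_rate[i])
    truth[[paste0("billed_", cid)]] <- billed
    bi <- which(billed)
    bill_rows[[cid]] <- tibble(
      patient_id = ids[bi],
      service_date = as.Date(runi(length(bi), ws, we), origin = "1970-01-01"),
      diag_code = defs$billing_codes[[cid]][1])
  }
  billing <- bind_rows(bill_rows)

  # --- assemble ---------------------------------------------------------
  patients <- tibble(
    patient_id = ids,
    sex = ifelse(missing_sex, NA_character_, sex),
    birth_date = as.Date(ifelse(missing_age, NA, birth), origin = "1970-01-01"))

  order_tab <- function(tb) {
    if (nrow(tb) == 0) return(tb)
    arrange(tb, dplyr::across(dplyr::everything()))
  }

  extract <- emr_extract(
    patients = patients,
    visits = order_tab(visits), problems = order_tab(problems),
    medications = order_tab(medications), labs = order_tab(labs),
    vitals = order_tab(vitals), billing = order_tab(billing),
    immunizations = order_tab(immunizations), allergies = order_tab(allergies),
    window_start = config$window_start, window_end = config$window_end,
    dialect = config$dialect)

  structure(list(extract = extract, ground_truth = truth, config = config),
            class = "synth_emr")
}

#' @export
print.synth_emr <- function(x, ...) {
  cat(sprintf("<synth_emr> %d patients, seed %d\n",
              x$config$n_patients, x$config$seed))
  print(x$extract)
  invisible(x)
}

#' Degrade an extract's quality
#'
#' Applies quality-reducing knobs only: deleting a fraction of a table's rows
#' and/or shifting vitals earlier in time. Every completeness and currency
#' measure on the degraded extract is at most its value on the original.
#'
#' @param extract An [emr_extract()].
#' @param drop Named list of fractions in `[0, 1]`: for each named record
#'   table, the fraction of rows to delete (1 deletes the table's rows
#'   entirely).
#' @param lag_vitals_days Shift all vitals this many days earlier (default 0).
#' @param seed Seed for the row-deletion draw.
#' @return A revalidated [emr_extract()].
#' @export
degrade_emr <- function(extract, drop = list(), lag_vitals_days = 0, seed = 1L) {
  stopifnot(inherits(extract, "emr_extract"))
  bad <- setdiff(names(drop), record_tables())
  if (length(bad) > 0) {
    abort(sprintf("Unknown record table(s) in `drop`: %s.",
                  paste(bad, collapse = ", ")))
  }
  withr::local_seed(seed)
  tabs <- stats::setNames(lapply(emr_schema()$table, function(nm) extract[[nm]]),
                          emr_schema()$table)
  for (nm in names(drop)) {
    frac <- drop[[nm]]
    tb <- tabs[[nm]]
    if (is.null(tb) || nrow(tb) == 0) next
    keep <- stats::runif(nrow(tb)) >= frac
    tabs[[nm]] <- tb[keep, ]
  }
  if (lag_vitals_days > 0 && !is.null(tabs$vitals)) {
    tabs$vitals$measure_date <- tabs$vitals$measure_date - lag_vitals_days
  }
  emr_extract(
    patients = tabs$patients, visits = tabs$visits, problems = tabs$problems,
    medications = tabs$medications, labs = tabs$labs, vitals = tabs$vitals,
    billing = tabs$billing, immunizations = tabs$immunizations,
    allergies = tabs$allergies,
    window_start = extract$window_start, window_end = extract$window_end,
    dialect = extract$dialect)
}
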