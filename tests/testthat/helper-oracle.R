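# Independent brute-force oracles written in plain base R. They deliberately
# avoid the package's vectorized machinery: set arithmetic, nested loops and
# textbook formulas only.

bf_chisq_gof <- function(observed, expected) {
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}

bf_chisq_indep <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}

bf_standardized_prevalence <- function(case_ids, cohort, standard,
                                       by_sex = TRUE) {
  strata_of <- function(i) {
    b <- as.character(age_band(cohort$index_age[i]))
    if (by_sex) paste(b, cohort$sex[i]) else b
  }
  strata <- vapply(seq_len(nrow(cohort)), strata_of, character(1))
  std_key <- if (by_sex) paste(as.character(standard$age_band), standard$sex)
             else as.character(standard$age_band)
  std_count <- tapply(standard$count, std_key, sum)
  num <- 0; den <- 0
  for (s in names(std_count)) {
    in_s <- strata == s
    n_s <- sum(in_s)
    if (n_s == 0) next
    r_s <- sum(cohort$patient_id[in_s] %in% case_ids) / n_s
    num <- num + std_count[[s]] * r_s
    den <- den + std_count[[s]]
  }
  100 * num / den
}

# Per-patient rule evaluation for the shipped default definitions, written
# as plain loops over one patient's records.
bf_is_case <- function(extract, cid, pid, index_age) {
  get <- function(nm) {
    tb <- extract[[nm]]
    if (is.null(tb)) tb else tb[tb$patient_id == pid, ]
  }
  norm <- function(x) {
    x <- tolower(x)
    x <- gsub("[[:punct:]]+", " ", x)
    trimws(gsub(" +", " ", x))
  }
  dict <- term_dictionary()
  tokens <- function(texts) {
    out <- norm(texts)
    for (i in seq_along(out)) {
      m <- which(dict$variant == out[i])
      if (length(m) > 0) out[i] <- dict$token[m[1]]
    }
    out
  }
  problems <- get("problems"); meds <- get("medications")
  labs <- get("labs"); vit <- get("vitals")

  has_problem <- function(tok) {
    !is.null(problems) && nrow(problems) > 0 && any(tokens(problems$text) == tok)
  }
  matched_drugs <- function(names) {
    if (is.null(meds) || nrow(meds) == 0) return(character())
    out <- character()
    for (i in seq_len(nrow(meds))) {
      for (nm in names) {
        if (grepl(nm, norm(meds$name[i]), fixed = TRUE)) out <- c(out, nm)
      }
    }
    unique(out)
  }
  lab_ge <- function(test, threshold) {
    !is.null(labs) && nrow(labs) > 0 &&
      any(labs$test_code == test & !is.na(labs$value) &
            labs$value >= threshold)
  }
  bp_high_dates <- function() {
    if (is.null(vit) || nrow(vit) == 0) return(character())
    days <- unique(as.character(vit$measure_date))
    out <- character()
    for (d in days) {
      s <- vit$value[vit$kind == "systolic_bp" & as.character(vit$measure_date) == d]
      dd <- vit$value[vit$kind == "diastolic_bp" & as.character(vit$measure_date) == d]
      if (length(s) > 0 && length(dd) > 0 &&
          (max(s) >= 140 || max(dd) >= 90)) out <- c(out, d)
    }
    out
  }
  bmi_ge30 <- function() {
    if (is.null(vit) || nrow(vit) == 0) return(FALSE)
    days <- unique(as.character(vit$measure_date))
    for (d in days) {
      h <- vit$value[vit$kind == "height" & as.character(vit$measure_date) == d]
      w <- vit$value[vit$kind == "weight" & as.character(vit$measure_date) == d]
      if (length(h) > 0 && length(w) > 0) {
        hm <- if (h[1] > 3) h[1] / 100 else h[1]
        if (w[1] / hm^2 >= 30) return(TRUE)
      }
    }
    FALSE
  }

  switch(cid,
    diabetes = has_problem("diabetes") ||
      length(matched_drugs(c("metformin", "glyburide", "gliclazide",
                             "sitagliptin", "insulin"))) >= 1 ||
      lab_ge("hba1c", 6.5) || lab_ge("glucose_fasting", 7.0),
    hypertension = has_problem("hypertension") ||
      length(matched_drugs(c("amlodipine", "ramipril", "lisinopril",
                             "candesartan", "metoprolol", "nifedipine",
                             "perindopril"))) >= 2 ||
      length(matched_drugs(c("hydrochlorothiazide", "furosemide",
                             "indapamide"))) >= 1 ||
      length(bp_high_dates()) >= 2,
    hypothyroidism = has_problem("hypothyroidism") ||
      length(matched_drugs(c("levothyroxine", "liothyronine",
                             "desiccated thyroid"))) >= 1,
    asthma = index_age <= 17 &&
      (has_problem("asthma") ||
         length(matched_drugs(c("salbutamol", "fluticasone", "budesonide",
                                "montelukast"))) >= 1),
    obesity = bmi_ge30() || has_problem("obesity"),
    urinary_tract_infection = {
      term <- has_problem("urinary_tract_infection")
      labmed <- FALSE
      if (!is.null(labs) && nrow(labs) > 0 && !is.null(meds) && nrow(meds) > 0) {
        pos <- labs$result_date[labs$test_code == "urine_culture" &
                                  !is.na(labs$qualitative) &
                                  labs$qualitative == "positive"]
        abx <- meds$start_date[grepl("nitrofurantoin|trimethoprim|ciprofloxacin|amoxicillin",
                                     norm(meds$name))]
        for (l in as.list(pos)) for (m in as.list(abx)) {
          if (m >= l && m <= l + 14) labmed <- TRUE
        }
      }
      term || labmed
    })
}

# Brute-force proportion of patients with >= 1 record of a vitals kind in an
# optional window before the last visit.
bf_vitals_pct <- function(extract, cohort, kind, window = NULL) {
  denom <- 0; num <- 0
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    if (kind == "bp" && cohort$index_age[i] < 18) next
    v <- extract$vitals[extract$vitals$patient_id == pid, ]
    lv <- extract$visits$visit_date[extract$visits$patient_id == pid]
    if (!is.null(window) && length(lv) == 0) next
    denom <- denom + 1
    dates <- if (kind == "bp") {
      ds <- unique(v$measure_date[v$kind == "systolic_bp"])
      dd <- unique(v$measure_date[v$kind == "diastolic_bp"])
      ds[ds %in% dd]
    } else unique(v$measure_date[v$kind == kind])
    if (!is.null(window)) {
      anchor <- max(lv)
      dates <- dates[dates >= anchor - window & dates <= anchor]
    }
    if (length(dates) > 0) num <- num + 1
  }
  list(numerator = num, denominator = denom,
       pct = if (denom > 0) 100 * num / denom else NA_real_)
}
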