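# Default case definitions for the six test conditions.
#
# These are editable starting points, not validated phenotyping algorithms:
# every threshold and term list is configuration, and users are expected to
# adapt them to their own extract. Clauses within a condition are a
# disjunction (any clause qualifies a patient); the onset date is the
# earliest date at which any clause is satisfied.
#
# Medication atoms match a drug when its class_code starts with one of
# `classes` or its normalized name contains one of `names`; `min_distinct`
# is the number of distinct qualifying drugs required.
conditions:
  diabetes:
    clauses:
      - problem_terms: [diabetes]
      - medication:
          classes: [antihyperglycemic]
          names: [metformin, glyburide, gliclazide, sitagliptin, insulin]
          min_distinct: 1
      - lab: {test: hba1c, op: ">=", threshold: 6.5, units: "%"}
      - lab: {test: glucose_fasting, op: ">=", threshold: 7.0, units: mmol/L}
  hypertension:
    clauses:
      - problem_terms: [hypertension]
      - medication:
          classes: [oral_antihypertensive]
          names: [amlodipine, ramipril, lisinopril, candesartan, metoprolol,
                  nifedipine, perindopril]
          min_distinct: 2
      - medication:
          classes: [diuretic]
          names: [hydrochlorothiazide, furosemide, indapamide]
          min_distinct: 1
      - bp: {systolic: 140, diastolic: 90, min_count: 2}
  hypothyroidism:
    clauses:
      - problem_terms: [hypothyroidism]
      - medication:
          classes: [thyroid_replacement]
          names: [levothyroxine, liothyronine, desiccated thyroid]
          min_distinct: 1
  asthma:
    age_max: 17  # index age < 18 years
    clauses:
      - problem_terms: [asthma]
      - medication:
          classes: [asthma_inhaler]
          names: [salbutamol, fluticasone, budesonide, montelukast]
          min_distinct: 1
  obesity:
    clauses:
      - bmi: {threshold: 30}
      - problem_terms: [obesity]
  urinary_tract_infection:
    clauses:
      - problem_terms: [urinary_tract_infection]
      - lab_med:
          test: urine_culture
          qualitative: positive
          med_classes: [antibiotic]
          med_names: [nitrofurantoin, trimethoprim, ciprofloxacin, amoxicillin]
          within_days: 14

# Diagnostic billing codes per condition (3-digit ICD-9 style), matched on
# exact string after trimming whitespace.
billing_codes:
  diabetes: ["250"]
  hypertension: ["401"]
  hypothyroidism: ["244"]
  asthma: ["493"]
  obesity: ["278"]
  urinary_tract_infection: ["599"]
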