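# Builders for small in-code cohorts used across test files.

ts <- function(x) adhera:::parse_timestamp(x)

# One-person cohort with an ICU encounter spanning [start_day, end_day]
# (whole days) and whatever events the caller supplies.
one_person_cohort <- function(person_id = "P1",
                              enc_start = "2020-06-01",
                              enc_end = "2020-06-30",
                              conditions = NULL, procedures = NULL,
                              drugs = NULL, observations = NULL) {
  cohort_data(
    persons = tibble::tibble(person_id = person_id, birth_year = 1950L,
                             sex = "female"),
    encounters = tibble::tibble(
      person_id = person_id, ward_type = "ICU",
      start = ts(enc_start), end = ts(paste0(enc_end, "T23:59:00"))),
    conditions = conditions, procedures = procedures,
    drug_administrations = drugs, observations = observations
  )
}

condition_rows <- function(person_id, code = "U07.1", onset, abatement = NA) {
  tibble::tibble(person_id = person_id, system = "ICD10", code = code,
                 onset = ts(onset),
                 abatement = if (all(is.na(abatement)))
                   ts(NA_character_) else ts(abatement))
}

drug_rows <- function(person_id, days, dose = 1, unit = "mg",
                      code = "H02AB02", hour = "09:00:00") {
  tibble::tibble(
    person_id = person_id, system = "ATC", code = code,
    dose_value = dose, dose_unit = unit,
    administered_at = ts(paste0(days, "T", hour)))
}

obs_rows <- function(person_id, at, value, unit = "%", code = "2708-6") {
  tibble::tibble(person_id = person_id, system = "LOINC", code = code,
                 value_num = value, value_unit = unit,
                 value_code = NA_character_, observed_at = ts(at))
}

dexa_criterion <- function(dose_mg = 1, freq = 1L, duration = 10) {
  criterion("drug_administration", concept_code("ATC", "H02AB02"),
            dosage = dosage_spec(quantity(dose_mg, "mg"),
                                 frequency_per_day = freq,
                                 duration_days = duration))
}

covid_criterion <- function() {
  criterion("condition", concept_code("ICD10", "U07.1"))
}

dosage_cohort_at <- function(days, dose = 1, unit = "mg") {
  one_person_cohort(enc_start = "2020-06-01", enc_end = "2020-06-30",
                    drugs = drug_rows("P1", format(days), dose, unit))
}

# day-sequence helper: "2020-06-01" + 0:9 etc.
days_from <- function(start, offsets) as.Date(start) + offsets

expect_day_results_equal <- function(a, b) {
  a <- a[order(a$person_id, a$date), ]
  b <- b[order(b$person_id, b$date), ]
  expect_identical(a$population_applicable, b$population_applicable)
  expect_identical(a$intervention_fulfilled, b$intervention_fulfilled)
  expect_identical(a$adherent, b$adherent)
}
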