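test_that("interval criteria cover days under the half-open convention", {
  co <- one_person_cohort(conditions = condition_rows("P1", onset = "2020-06-03"))
  crit <- covid_criterion()
  expect_false(evaluate_criterion(crit, co, "P1", "2020-06-02"))
  expect_true(evaluate_criterion(crit, co, "P1", "2020-06-03"))
  # open-ended condition extends forward
  expect_true(evaluate_criterion(crit, co, "P1", "2020-06-25"))

  co2 <- one_person_cohort(conditions = condition_rows(
    "P1", onset = "2020-06-03", abatement = "2020-06-07"))
  expect_true(evaluate_criterion(crit, co2, "P1", "2020-06-06"))
  # abatement at 00:00 of day 7: day 7 is not covered
  expect_false(evaluate_criterion(crit, co2, "P1", "2020-06-07"))
})

test_that("closed world: absent data is false, negation flips it", {
  co <- one_person_cohort()
  drug <- criterion("drug_administration", concept_code("ATC", "H02AB02"))
  expect_false(evaluate_criterion(drug, co, "P1", "2020-06-05"))
  drug_neg <- criterion("drug_administration", concept_code("ATC", "H02AB02"),
                        negated = TRUE)
  expect_true(evaluate_criterion(drug_neg, co, "P1", "2020-06-05"))
  expect_error(evaluate_criterion(drug, co, "P9", "2020-06-05"),
               class = "adhera_data_error")
})

test_that("observation criteria use the most recent value before day end", {
  spo2 <- criterion("observation", concept_code("LOINC", "2708-6"),
                    comparator = "<", threshold = quantity(94, "%"))
  co <- one_person_cohort(observations = obs_rows(
    "P1", c("2020-06-02T08:00:00", "2020-06-04T08:00:00"), c(96, 92)))
  expect_false(evaluate_criterion(spo2, co, "P1", "2020-06-01")) # nothing yet
  expect_false(evaluate_criterion(spo2, co, "P1", "2020-06-03")) # 96, not <94
  expect_true(evaluate_criterion(spo2, co, "P1", "2020-06-04"))  # 92 < 94
  expect_true(evaluate_criterion(spo2, co, "P1", "2020-06-20"))  # carried forward

  # enumerated comparator truth table on the last value (92 %)
  for (case in list(list("<", 94, TRUE), list("<=", 92, TRUE),
                    list("=", 92, TRUE), list(">=", 93, FALSE),
                    list(">", 92, FALSE))) {
    crit <- criterion("observation", concept_code("LOINC", "2708-6"),
                      comparator = case[[1]],
                      threshold = quantity(case[[2]], "%"))
    expect_equal(evaluate_criterion(crit, co, "P1", "2020-06-10"), case[[3]],
                 label = paste("op", case[[1]]))
  }
})

test_that("combinations follow boolean semantics regardless of member order", {
  co <- one_person_cohort(conditions = condition_rows("P1", onset = "2020-06-01"))
  truthy <- covid_criterion()
  falsy <- criterion("condition", concept_code("ICD10", "I10"))
  d <- "2020-06-05"
  expect_false(evaluate_combination(
    criterion_group("ALL_OF", list(truthy, falsy)), co, "P1", d))
  expect_true(evaluate_combination(
    criterion_group("ANY_OF", list(truthy, falsy)), co, "P1", d))
  expect_true(evaluate_combination(
    criterion_group("ANY_OF", list(falsy, truthy)), co, "P1", d))
  expect_false(evaluate_combination(
    criterion_group("ALL_OF", list(truthy, truthy), negated = TRUE),
    co, "P1", d))
  # nested De Morgan spot check: NOT(ANY_OF[falsy, NOT(truthy)]) == truthy
  nested <- criterion_group("ANY_OF", list(
    falsy, criterion("condition", concept_code("ICD10", "U07.1"),
                     negated = TRUE)), negated = TRUE)
  expect_true(evaluate_combination(nested, co, "P1", d))
})

test_that("compilation resolves codes, fails strictly with a path, and is pure", {
  rec <- example_recommendation()
  cm <- load_codemap(system.file("extdata", "codemap-identity.csv",
                                 package = "adhera"))
  plan <- compile_plan(rec, cm)
  expect_length(adhera:::plan_leaves(plan$population), 2L)
  expect_length(adhera:::plan_leaves(plan$intervention), 1L)
  expect_equal(compile_plan(rec, cm), plan) # deterministic

  # strict map missing the drug code: error located at the criterion path
  cm_nodrug <- codemap(cm$entries[cm$entries$guideline_code != "H02AB02", ])
  err <- expect_error(compile_plan(rec, cm_nodrug),
                      class = "adhera_compile_error")
  expect_equal(err$path, "/intervention/members/0")

  # purity: compiling is independent of any cohort content
  expect_equal(compile_plan(rec, cm), plan)
})

test_that("applicability is gated on an active encounter", {
  window <- evaluation_window("2020-06-01", "2020-06-20")
  plan <- compile_plan(example_recommendation())
  # covid + oxygen all window, but no encounter rows at all
  co <- cohort_data(
    persons = tibble::tibble(person_id = "P1", birth_year = 1950L, sex = "f"),
    conditions = condition_rows("P1", onset = "2020-06-01"),
    procedures = tibble::tibble(
      person_id = "P1", system = "SNOMED", code = "57485005",
      start = ts("2020-06-01"), end = ts(NA_character_)))
  res <- evaluate_patient(plan, co, "P1", window)
  expect_equal(nrow(res), 20L)
  expect_false(any(res$population_applicable))
  expect_false(any(res$adherent))
  # intervention is still evaluated on its own
  expect_false(any(res$intervention_fulfilled))
})

test_that("a mid-window course yields adherence exactly on its course days", {
  window <- evaluation_window("2020-06-01", "2020-06-20")
  plan <- compile_plan(example_recommendation())
  co <- one_person_cohort(
    enc_start = "2020-06-01", enc_end = "2020-06-20",
    conditions = condition_rows("P1", onset = "2020-06-01"),
    procedures = tibble::tibble(
      person_id = "P1", system = "SNOMED", code = "57485005",
      start = ts("2020-06-01"), end = ts(NA_character_)),
    drugs = drug_rows("P1", format(days_from("2020-06-05", 0:9))))
  res <- evaluate_patient(plan, co, "P1", window)
  expect_true(all(res$population_applicable))
  expect_equal(res$date[res$adherent], days_from("2020-06-05", 0:9))
  # day-by-day brute force agrees
  nv <- evaluate_cohort_naive(example_recommendation(), co, window)
  expect_day_results_equal(res, nv$day_results)
})

test_that("cohort aggregation counts applicable and adherent patients per day", {
  gen <- generate_cohort(scenario_config(n_patients = 40L, seed = 5L))
  plan <- compile_plan(example_recommendation())
  window <- evaluation_window("2020-03-01", "2021-05-31")
  ev <- evaluate_cohort(plan, gen$cohort, window, keep_leaf_results = FALSE)
  # recount independently from day results
  expect_equal(ev$series, recount_series(ev$day_results))
  # subset law every day
  expect_true(all(ev$series$n_adherent <= ev$series$n_applicable))
  # fraction undefined exactly when nobody is applicable
  expect_identical(is.na(ev$series$fraction), ev$series$n_applicable == 0L)
})

test_that("an empty cohort yields an all-zero series with undefined fractions", {
  ev <- evaluate_cohort(compile_plan(example_recommendation()),
                        cohort_data(),
                        evaluation_window("2020-06-01", "2020-06-10"))
  expect_equal(nrow(ev$series), 10L)
  expect_true(all(ev$series$n_applicable == 0L))
  expect_true(all(is.na(ev$series$fraction)))
})

test_that("results are invariant to patient processing order", {
  inst <- random_instance(77)
  plan <- compile_plan(inst$rec)
  ev1 <- evaluate_cohort(plan, inst$cohort, inst$window,
                         keep_leaf_results = FALSE)
  co2 <- inst$cohort
  co2$persons <- co2$persons[rev(seq_len(nrow(co2$persons))), ]
  ev2 <- evaluate_cohort(plan, co2, inst$window, keep_leaf_results = FALSE)
  expect_equal(ev1$series, ev2$series)
})

test_that("tidy, glance and autoplot expose the evaluation", {
  gen <- generate_cohort(scenario_config(n_patients = 15L, seed = 2L))
  ev <- evaluate_cohort(compile_plan(example_recommendation()), gen$cohort,
                        evaluation_window("2020-03-01", "2020-12-31"))
  expect_equal(tidy(ev), ev$series)
  g <- glance(ev)
  expect_equal(g$n_patients, 15L)
  expect_equal(g$patient_days_adherent, sum(ev$series$n_adherent))
  skip_if_not_installed("patchwork")
  p <- autoplot(ev, switch_date = "2020-06-16")
  expect_s3_class(p, "patchwork")
})
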