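# Course-based dosage semantics for the worked regimen: one 1 mg
# administration per day for 10 days. Each scenario is checked on every day
# of a 30-day window against the enumerated-course-start brute-force oracle,
# plus hand-derived spot expectations.

dosage_cohort <- function(days, dose = 1, unit = "mg") {
  one_person_cohort(enc_start = "2020-06-01", enc_end = "2020-06-30",
                    drugs = drug_rows("P1", format(days), dose, unit))
}

days_in_window <- days_from("2020-06-01", 0:29)

eval_all_days <- function(co, crit) {
  vapply(format(days_in_window), function(d)
    evaluate_dosage(crit, co, "P1", d), logical(1), USE.NAMES = FALSE)
}

oracle_all_days <- function(co, crit) {
  rec <- recommendation(
    "dosage-probe", "probe", "1", "2020-01-01",
    population = criterion_group("ALL_OF", list(covid_criterion())),
    intervention = criterion_group("ALL_OF", list(crit)))
  nv <- evaluate_cohort_naive(rec, co,
                              evaluation_window("2020-06-01", "2020-06-30"))
  nv$day_results$intervention_fulfilled[order(nv$day_results$date)]
}

test_that("course scenarios match the brute-force oracle on every day", {
  crit <- dexa_criterion()
  scenarios <- list(
    complete = dosage_cohort(days_from("2020-06-03", 0:9)),
    mid_course_truncated = dosage_cohort(days_from("2020-06-25", 0:5)),
    gapped = dosage_cohort(days_from("2020-06-03", c(0, 1, 3:9))),
    wrong_dose = dosage_cohort(days_from("2020-06-03", 0:9), dose = 3),
    over_long = dosage_cohort(days_from("2020-06-03", 0:14)),
    two_courses = dosage_cohort(days_from("2020-06-01", c(0:2, 14:18))),
    no_drug = one_person_cohort()
  )
  for (nm in names(scenarios)) {
    expect_equal(eval_all_days(scenarios[[nm]], crit),
                 oracle_all_days(scenarios[[nm]], crit), label = nm)
  }
})

test_that("complete and mid-course days are fulfilled, later days are not", {
  crit <- dexa_criterion()
  co <- dosage_cohort(days_from("2020-06-03", 0:9))
  got <- eval_all_days(co, crit)
  expect_equal(days_in_window[got], days_from("2020-06-03", 0:9))
  # mid-course (ongoing-adherent): day 4 of the course is fulfilled
  expect_true(got[days_in_window == as.Date("2020-06-06")])
  # the day after the completed course is not
  expect_false(got[days_in_window == as.Date("2020-06-13")])
})

test_that("a gap breaks every course that spans it", {
  crit <- dexa_criterion()
  co <- dosage_cohort(days_from("2020-06-01", c(0, 1, 3, 4)))
  got <- eval_all_days(co, crit)
  # days 1-2 fulfilled from the fresh start; post-gap days belong to no
  # fresh course (the washout window still contains administrations)
  expect_equal(days_in_window[got], days_from("2020-06-01", 0:1))
  expect_false(got[days_in_window == as.Date("2020-06-05")])
})

test_that("an over-long run stops being fulfilled after duration_days", {
  crit <- dexa_criterion()
  co <- dosage_cohort(days_from("2020-06-03", 0:14))
  got <- eval_all_days(co, crit)
  expect_equal(days_in_window[got], days_from("2020-06-03", 0:9))
})

test_that("daily total dose is checked within the relative tolerance", {
  crit <- dexa_criterion()
  expect_true(eval_all_days(
    dosage_cohort(days_from("2020-06-03", 0:9), dose = 1.05), crit)[5])
  expect_false(any(eval_all_days(
    dosage_cohort(days_from("2020-06-03", 0:9), dose = 1.5), crit)))
  # unit normalisation: 1000 ug == 1 mg
  expect_true(eval_all_days(
    dosage_cohort(days_from("2020-06-03", 0:9), dose = 1000, unit = "ug"),
    crit)[5])
})

test_that("frequency_per_day requires the exact administration count", {
  crit2 <- dexa_criterion(freq = 2L, duration = 5)
  co_once <- dosage_cohort(days_from("2020-06-03", 0:4))
  expect_false(any(eval_all_days(co_once, crit2)))
  twice <- dplyr::bind_rows(
    drug_rows("P1", format(days_from("2020-06-03", 0:4)), hour = "09:00:00"),
    drug_rows("P1", format(days_from("2020-06-03", 0:4)), hour = "21:00:00"))
  co_twice <- one_person_cohort(drugs = twice)
  got <- eval_all_days(co_twice, crit2)
  expect_equal(days_in_window[got], days_from("2020-06-03", 0:4))
  expect_equal(got, oracle_all_days(co_twice, crit2))
})

test_that("unbounded courses stay fulfilled while the daily pattern holds", {
  crit <- dexa_criterion(duration = Inf)
  co <- dosage_cohort(days_from("2020-06-03", 0:19))
  got <- eval_all_days(co, crit)
  expect_equal(days_in_window[got], days_from("2020-06-03", 0:19))
  expect_equal(got, oracle_all_days(co, crit))
})

test_that("incomparable dose units raise an error naming both units", {
  crit <- dexa_criterion()
  co <- dosage_cohort(days_from("2020-06-03", 0:9), dose = 50, unit = "%")
  err <- expect_error(eval_all_days(co, crit), class = "adhera_unit_error")
  expect_match(conditionMessage(err), "%", fixed = TRUE)
  expect_match(conditionMessage(err), "mg")
})
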