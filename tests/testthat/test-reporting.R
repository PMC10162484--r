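fixture_series_expected <- tibble::tibble(
  date = days_from("2020-06-01", 0:29),
  n_applicable = c(1L, 1L, 2L, 2L, 3L, 3L, 3L, 3L, 3L, 3L,
                   2L, 2L, 1L, 1L, rep(0L, 16)),
  n_adherent = c(1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L,
                 0L, 0L, 0L, 0L, rep(0L, 16))
) |>
  dplyr::mutate(fraction = ifelse(n_applicable > 0,
                                  n_adherent / n_applicable, NA_real_))

run_fixture <- function(out_dir) {
  run_evaluation(
    system.file("extdata", "recommendation-dexamethasone.json",
                package = "adhera"),
    system.file("extdata", "fixture-cohort", package = "adhera"),
    evaluation_window("2020-06-01", "2020-06-30"),
    out_dir,
    codemap_path = system.file("extdata", "codemap-identity.csv",
                               package = "adhera"))
}

test_that("the bundled fixture reproduces the hand-computed series", {
  out <- withr::local_tempdir()
  ev <- run_fixture(out)
  expect_equal(ev$series, fixture_series_expected)
  written <- readr::read_csv(
    file.path(out, "series.csv"),
    col_types = readr::cols(date = readr::col_date(),
                            .default = readr::col_character()))
  expect_equal(nrow(written), 30L)
  expect_equal(written$fraction[5], "0.333333")  # six decimals
  expect_true(is.na(written$fraction[20]))       # undefined -> empty
  expect_true(file.exists(file.path(out, "report.json")))
  report <- jsonlite::fromJSON(file.path(out, "report.json"))
  expect_equal(report$recommendation$id, "covid19-dexamethasone")
  expect_equal(report$summary$patient_days_adherent, 11L)
})

test_that("outputs are byte-identical across runs of the same inputs", {
  o1 <- withr::local_tempdir()
  o2 <- withr::local_tempdir()
  run_fixture(o1)
  run_fixture(o2)
  for (f in c("series.csv", "day_results.csv", "leaf_results.csv",
              "report.json")) {
    expect_identical(readLines(file.path(o1, f)),
                     readLines(file.path(o2, f)), label = f)
  }
})

test_that("series.csv recounts exactly from day_results.csv", {
  out <- withr::local_tempdir()
  run_fixture(out)
  day_results <- readr::read_csv(
    file.path(out, "day_results.csv"),
    col_types = readr::cols(
      person_id = readr::col_character(), date = readr::col_date(),
      .default = readr::col_logical()))
  recounted <- recount_series(day_results)
  series <- readr::read_csv(
    file.path(out, "series.csv"),
    col_types = readr::cols(date = readr::col_date(),
                            n_applicable = readr::col_integer(),
                            n_adherent = readr::col_integer(),
                            fraction = readr::col_double()))
  expect_equal(series$n_applicable, recounted$n_applicable)
  expect_equal(series$n_adherent, recounted$n_adherent)
  expect_equal(series$fraction, round(recounted$fraction, 6))
})

test_that("leaf_results.csv suffices to reconstruct every day verdict", {
  out <- withr::local_tempdir()
  ev <- run_fixture(out)
  leaves <- readr::read_csv(
    file.path(out, "leaf_results.csv"),
    col_types = readr::cols(
      person_id = readr::col_character(), date = readr::col_date(),
      criterion_path = readr::col_character(),
      result = readr::col_logical()))
  wide <- tidyr::pivot_wider(leaves, names_from = "criterion_path",
                             values_from = "result")
  wide <- wide[order(wide$person_id, wide$date), ]
  dr <- ev$day_results[order(ev$day_results$person_id, ev$day_results$date), ]
  # re-apply the boolean trees: population = ALL_OF of its two leaves,
  # intervention = its single dosage leaf; applicability needs admission
  pop <- wide[["/population/members/0"]] & wide[["/population/members/1"]]
  intv <- wide[["/intervention/members/0"]]
  expect_identical(dr$intervention_fulfilled, intv)
  expect_true(all(dr$population_applicable <= pop))
  expect_identical(dr$adherent, dr$population_applicable & intv)
})

test_that("missing inputs fail loudly and leave no partial outputs", {
  out <- file.path(withr::local_tempdir(), "results")
  err <- expect_error(
    run_evaluation(
      system.file("extdata", "recommendation-dexamethasone.json",
                  package = "adhera"),
      system.file("extdata", "fixture-cohort", package = "adhera"),
      evaluation_window("2020-06-01", "2020-06-30"),
      out, codemap_path = "/nonexistent/codemap.csv"),
    class = "adhera_io_error")
  expect_match(conditionMessage(err), "/nonexistent/codemap.csv")
  expect_false(dir.exists(out))
})

test_that("run_synthetic writes cohort, ground truth and evaluation", {
  cfgfile <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_patients: 20", "seed: 6",
               "window:", "  start_date: 2020-03-01",
               "  end_date: 2020-12-31"), cfgfile)
  out <- withr::local_tempdir()
  gen <- run_synthetic(cfgfile, out, evaluate = TRUE)
  expect_true(all(file.exists(file.path(out, adhera:::cohort_file_names()))))
  expect_true(file.exists(file.path(out, "ground_truth.csv")))
  expect_true(file.exists(file.path(out, "evaluation", "series.csv")))
  reloaded <- load_cohort(out)
  expect_equal(reloaded, gen$cohort)

  # determinism across runs
  out2 <- withr::local_tempdir()
  run_synthetic(cfgfile, out2)
  expect_identical(readLines(file.path(out, "ground_truth.csv")),
                   readLines(file.path(out2, "ground_truth.csv")))
})
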