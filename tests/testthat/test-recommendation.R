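bundled_doc <- function() {
  system.file("extdata", "recommendation-dexamethasone.json",
              package = "adhera")
}

test_that("the worked dexamethasone document parses into the expected trees", {
  rec <- parse_recommendation(bundled_doc())
  expect_s3_class(rec, "recommendation")
  expect_equal(rec$id, "covid19-dexamethasone")
  expect_equal(rec$valid_from, as.Date("2020-06-16"))

  pop <- rec$population
  expect_equal(pop$operator, "ALL_OF")
  expect_length(pop$members, 2L)
  expect_equal(pop$members[[1]]$kind, "condition")
  expect_equal(pop$members[[1]]$concept$code, "U07.1")
  expect_equal(pop$members[[2]]$kind, "procedure_active")
  expect_equal(pop$members[[2]]$concept$system, "SNOMED")

  drug <- rec$intervention$members[[1]]
  expect_equal(drug$kind, "drug_administration")
  expect_equal(drug$concept$code, "H02AB02")
  expect_equal(drug$dosage$dose$value, 1)
  expect_equal(drug$dosage$dose$unit$code, "mg")
  expect_equal(drug$dosage$frequency_per_day, 1L)
  expect_equal(drug$dosage$duration_days, 10)
})

test_that("schema violations are located by JSON path", {
  doc <- jsonlite::fromJSON(readLines(bundled_doc()), simplifyVector = FALSE)
  doc$intervention <- NULL
  err <- expect_error(
    parse_recommendation(jsonlite::toJSON(doc, auto_unbox = TRUE)),
    class = "adhera_schema_error")
  expect_equal(err$path, "/intervention")

  doc2 <- jsonlite::fromJSON(readLines(bundled_doc()), simplifyVector = FALSE)
  doc2$population$members[[1]]$concept$system <- "MESH"
  err2 <- expect_error(
    parse_recommendation(jsonlite::toJSON(doc2, auto_unbox = TRUE)),
    class = "adhera_schema_error")
  expect_match(err2$path, "^/population/members/0/concept")

  doc3 <- jsonlite::fromJSON(readLines(bundled_doc()), simplifyVector = FALSE)
  doc3$population$members <- list()
  err3 <- expect_error(
    parse_recommendation(jsonlite::toJSON(doc3, auto_unbox = TRUE)),
    class = "adhera_schema_error")
  expect_match(err3$path, "^/population")
})

test_that("unknown top-level fields are ignored with a warning", {
  doc <- jsonlite::fromJSON(readLines(bundled_doc()), simplifyVector = FALSE)
  doc$evidence_certainty <- "moderate"
  expect_warning(
    rec <- parse_recommendation(jsonlite::toJSON(doc, auto_unbox = TRUE)),
    "evidence_certainty")
  expect_s3_class(rec, "recommendation")
})

test_that("PICO comparison/outcome elements are accepted silently", {
  doc <- jsonlite::fromJSON(readLines(bundled_doc()), simplifyVector = FALSE)
  doc$comparison <- list(note = "standard of care")
  doc$outcome <- list(note = "28-day mortality")
  expect_no_warning(rec <- parse_recommendation(
    jsonlite::toJSON(doc, auto_unbox = TRUE)))
  expect_s3_class(rec, "recommendation")
})

test_that("serialization is deterministic and round-trips structurally", {
  rec <- example_recommendation()
  j1 <- serialize_recommendation(rec)
  j2 <- serialize_recommendation(rec)
  expect_identical(j1, j2)
  expect_equal(parse_recommendation(j1), rec)
})

test_that("random recommendations survive the JSON round trip", {
  withr::with_seed(42, {
    for (i in 1:25) {
      rec <- random_recommendation(max_depth = 4L)
      expect_equal(parse_recommendation(serialize_recommendation(rec)), rec)
    }
  })
})

test_that("select_version picks the latest version valid on the date", {
  v1 <- example_recommendation(version = "1.0.0", valid_from = "2020-06-16")
  v2 <- example_recommendation(dose_mg = 2, version = "2.0.0",
                               valid_from = "2021-02-01")
  versions <- list(v1, v2)

  expect_equal(select_version(versions, "2020-12-01")$version, "1.0.0")
  expect_equal(select_version(versions, "2021-03-01")$version, "2.0.0")
  # inclusive boundary: a version applies on its own valid_from day
  expect_equal(select_version(versions, "2021-02-01")$version, "2.0.0")
  expect_null(select_version(versions, "2020-01-01"))
  # order independence and idempotence
  expect_equal(select_version(rev(versions), "2020-12-01")$version, "1.0.0")
  expect_equal(select_version(list(v1), "2020-12-01")$version, "1.0.0")
})

test_that("select_version rejects mixed ids and duplicate valid_from", {
  v1 <- example_recommendation()
  v2 <- example_recommendation(dose_mg = 2, version = "2.0.0")
  other <- recommendation("other-rec", "t", "1", "2020-01-01",
                          v1$population, v1$intervention)
  expect_error(select_version(list(v1, other), "2021-01-01"),
               class = "adhera_version_error")
  expect_error(select_version(list(v1, v2), "2021-01-01"),
               class = "adhera_version_error")
})
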