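#' Summarise adherence per patient
#'
#' Collapses day-level results to one row per patient: how many days the
#' recommendation was applicable, how many of those were adherent, whether
#' any day was adherent, and whether the patient was adherent on *every*
#' applicable day (`fully_adherent`; `FALSE` for patients with no applicable
#' day). The last is the patient-level notion of "treated according to the
#' recommendation" used in cohort adherence-rate estimates.
#'
#' @param day_results Tibble as produced by [evaluate_patient()] /
#'   [evaluate_cohort()] (`$day_results`), or a `cohort_evaluation`.
#' @return A tibble with columns `person_id`, `n_applicable_days`,
#'   `n_adherent_days`, `any_adherent`, `fully_adherent`.
#' @export
summarize_patient_adherence <- function(day_results) {
  if (inherits(day_results, "cohort_evaluation")) {
    day_results <- day_results$day_results
  }
  day_results |>
    dplyr::group_by(person_id = .data$person_id) |>
    dplyr::summarise(
      n_applicable_days = sum(.data$population_applicable),
      n_adherent_days = sum(.data$adherent),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      any_adherent = .data$n_adherent_days > 0L,
      fully_adherent = .data$n_applicable_days > 0L &
        .data$n_adherent_days == .data$n_applicable_days
    )
}

#' Patient-level adherence fraction by treatment regime
#'
#' Splits applicable patients into a pre- and post-`switch_date` regime by
#' their admission date (first encounter start; the switch day itself opens
#' the new regime) and reports, per regime, the number of applicable
#' patients, the number adherent on every applicable day, and their
#' fraction. This is the estimator that recovers a configured per-patient
#' adherence probability from generated data, and the quantity whose step
#' change across the switch date reproduces a guideline-introduction
#' scenario.
#'
#' @param evaluation A `cohort_evaluation` (or a `day_results` tibble).
#' @param cohort The [cohort_data()] that was evaluated (for admissions).
#' @param switch_date `Date` or `"YYYY-MM-DD"`.
#' @return A tibble with columns `regime` (`"before"`/`"after"`),
#'   `n_applicable_patients`, `n_adherent_patients`, `fraction`.
#' @export
adherence_by_regime <- function(evaluation, cohort, switch_date) {
  switch_date <- as_calendar_date(switch_date, "switch_date")
  per_patient <- summarize_patient_adherence(evaluation)
  admissions <- cohort$encounters |>
    dplyr::group_by(person_id = .data$person_id) |>
    dplyr::summarise(admission = as.Date(min(.data$start)), .groups = "drop")
  per_patient |>
    dplyr::filter(.data$n_applicable_days > 0L) |>
    dplyr::inner_join(admissions, by = "person_id") |>
    dplyr::mutate(regime = dplyr::if_else(.data$admission < switch_date,
                                          "before", "after")) |>
    dplyr::group_by(regime = .data$regime) |>
    dplyr::summarise(
      n_applicable_patients = dplyr::n(),
      n_adherent_patients = sum(.data$fully_adherent),
      .groups = "drop"
    ) |>
    dplyr::mutate(fraction = .data$n_adherent_patients /
                    .data$n_applicable_patients) |>
    dplyr::arrange(factor(.data$regime, levels = c("before", "after")))
}

#' Run a full evaluation from files to files
#'
#' The end-to-end entry point behind the command line: load and validate the
#' recommendation document, cohort directory and (optional) code map,
#' compile, evaluate over the window, and write the results:
#' `series.csv` (`date,n_applicable,n_adherent,fraction` — fractions with 6
#' decimals, empty when undefined), `day_results.csv`, `leaf_results.csv`
#' (per-criterion truth values for raw-data review) and `report.json`.
#' Outputs are deterministic: the same inputs produce byte-identical files.
#' Any validation failure raises before anything is written, so no partial
#' outputs are left behind.
#'
#' @param recommendation_path Path to a recommendation JSON document.
#' @param cohort_dir Directory with the six cohort CSVs.
#' @param window An [evaluation_window()].
#' @param out_dir Output directory (created if needed).
#' @param codemap_path Optional path to a mapping CSV; when `NULL` the
#'   identity mapping is used.
#' @param strict_codes Logical; error on unmapped concepts (default `TRUE`
#'   when a code map is given).
#' @param dose_tolerance Relative daily-dose tolerance (default 0.10).
#' @return The `cohort_evaluation`, invisibly, with the written report
#'   attached as attribute `"report"`.
#' @export
run_evaluation <- function(recommendation_path, cohort_dir, window, out_dir,
                           codemap_path = NULL, strict_codes = TRUE,
                           dose_tolerance = 0.1) {
  stopifnot(inherits(window, "evaluation_window"))
  if (!file.exists(recommendation_path)) {
    stop_adhera(sprintf("recommendation file not found: %s",
                        recommendation_path),
                class = "adhera_io_error")
  }
  rec <- parse_recommendation(recommendation_path)
  map <- if (is.null(codemap_path)) {
    identity_codemap()
  } else {
    load_codemap(codemap_path, strict = strict_codes)
  }
  cohort <- load_cohort(cohort_dir)
  plan <- compile_plan(rec, map, dose_tolerance = dose_tolerance)
  evaluation <- evaluate_cohort(plan, cohort, window,
                                keep_leaf_results = TRUE)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  series_out <- evaluation$series |>
    dplyr::mutate(fraction = ifelse(is.na(.data$fraction), NA_character_,
                                    sprintf("%.6f", .data$fraction)))
  readr::write_csv(series_out, file.path(out_dir, "series.csv"),
                   na = "", progress = FALSE)
  readr::write_csv(evaluation$day_results,
                   file.path(out_dir, "day_results.csv"),
                   na = "", progress = FALSE)
  readr::write_csv(evaluation$leaf_results,
                   file.path(out_dir, "leaf_results.csv"),
                   na = "", progress = FALSE)

  report <- list(
    recommendation = list(id = rec$id, version = rec$version,
                          valid_from = format(rec$valid_from)),
    window = list(start_date = format(window$start_date),
                  end_date = format(window$end_date)),
    config = list(
      recommendation_path = as.character(recommendation_path),
      cohort_dir = as.character(cohort_dir),
      codemap_path = if (is.null(codemap_path)) NULL
                     else as.character(codemap_path),
      strict_codes = isTRUE(strict_codes),
      dose_tolerance = dose_tolerance
    ),
    summary = as.list(generics::glance(evaluation)),
    tool = list(package = "adhera",
                version = as.character(utils::packageVersion("adhera")))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  attr(evaluation, "report") <- report
  invisible(evaluation)
}

#' Generate a synthetic scenario from a config file
#'
#' Reads a [scenario_config()] from YAML/JSON, generates the cohort, and
#' writes the six cohort CSVs plus `ground_truth.csv` to `out_dir`.
#' Optionally runs the bundled example recommendation over the generated
#' cohort in one step, writing evaluation outputs to
#' `file.path(out_dir, "evaluation")`.
#'
#' @param config_path Path to a scenario config (YAML or JSON).
#' @param out_dir Output directory.
#' @param evaluate Logical; also run the evaluation (default `FALSE`).
#' @return The generated list (`cohort`, `ground_truth`), invisibly.
#' @export
run_synthetic <- function(config_path, out_dir, evaluate = FALSE) {
  config <- read_scenario_config(config_path)
  gen <- generate_cohort(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(gen$cohort, out_dir)
  gt <- gen$ground_truth |>
    dplyr::mutate(dplyr::across(dplyr::where(is_date_col), format_date_col))
  readr::write_csv(gt, file.path(out_dir, "ground_truth.csv"),
                   na = "", progress = FALSE)
  if (evaluate) {
    rec_path <- file.path(out_dir, "recommendation.json")
    serialize_recommendation(example_recommendation(), rec_path)
    run_evaluation(rec_path, out_dir, config$window,
                   file.path(out_dir, "evaluation"))
  }
  invisible(gen)
}

is_date_col <- function(x) inherits(x, "Date")
format_date_col <- function(x) ifelse(is.na(x), NA_character_,
                                      format(x, "%Y-%m-%d"))

#' Recount a series from day results
#'
#' Independent aggregation used for internal consistency checks: recomputes
#' `n_applicable` / `n_adherent` / `fraction` per day by plain counting over
#' a `day_results` table.
#'
#' @param day_results Tibble with day-level results.
#' @return A series tibble.
#' @export
recount_series <- function(day_results) {
  agg_app <- stats::aggregate(population_applicable ~ date,
                              data = day_results, FUN = sum)
  agg_adh <- stats::aggregate(adherent ~ date, data = day_results, FUN = sum)
  out <- merge(agg_app, agg_adh, by = "date")
  out <- out[order(out$date), ]
  tibble::tibble(
    date = out$date,
    n_applicable = as.integer(out$population_applicable),
    n_adherent = as.integer(out$adherent),
    fraction = ifelse(out$population_applicable > 0,
                      out$adherent / out$population_applicable, NA_real_)
  )
}
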