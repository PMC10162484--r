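#' The common data model tables
#'
#' Clinical data enter the engine as six tables — persons, encounters,
#' conditions, drug administrations, observations, procedures — in a minimal
#' common data model, so that evaluation is independent of any hospital's
#' proprietary system. Any source (an OMOP database, a FHIR server, a ward
#' information system export) can feed the engine once an ETL step produces
#' these tables.
#'
#' All timestamps are timezone-naive local datetimes (stored as UTC
#' `POSIXct`); a date-only value means 00:00 of that day. Intervals are
#' half-open `[start, end)`: an event ending at 00:00 of day *d* does not
#' cover day *d*. Open-ended intervals (`end` missing) extend to the end of
#' the evaluation window.
#'
#' @param persons Tibble with columns `person_id` (chr), `birth_year` (int),
#'   `sex` (chr, may be `NA`).
#' @param encounters Tibble with `person_id`, `ward_type` (chr), `start`,
#'   `end` (POSIXct, `end` may be `NA`).
#' @param conditions Tibble with `person_id`, `system`, `code`, `onset`,
#'   `abatement`.
#' @param drug_administrations Tibble with `person_id`, `system`, `code`,
#'   `dose_value` (dbl), `dose_unit` (chr, UCUM), `administered_at`.
#' @param observations Tibble with `person_id`, `system`, `code`,
#'   `value_num` (dbl), `value_unit` (chr), `value_code` (chr),
#'   `observed_at`; exactly one of `value_num`/`value_code` per row.
#' @param procedures Tibble with `person_id`, `system`, `code`, `start`,
#'   `end`.
#' @return An object of class `cohort_data`: a named list of the six tibbles.
#' @seealso [load_cohort()], [write_cohort()], [validate_cohort()]
#' @export
cohort_data <- function(persons = NULL, encounters = NULL, conditions = NULL,
                        drug_administrations = NULL, observations = NULL,
                        procedures = NULL) {
  tabs <- list(
    persons = persons %||% empty_table("persons"),
    encounters = encounters %||% empty_table("encounters"),
    conditions = conditions %||% empty_table("conditions"),
    drug_administrations = drug_administrations %||% empty_table("drug_administrations"),
    observations = observations %||% empty_table("observations"),
    procedures = procedures %||% empty_table("procedures")
  )
  tabs <- purrr::imap(tabs, function(tab, nm) {
    spec <- .cdm_columns[[nm]]
    missing <- setdiff(names(spec), names(tab))
    if (length(missing) > 0L) {
      stop_adhera(sprintf("table '%s' is missing column(s): %s",
                          nm, paste(missing, collapse = ", ")),
                  class = "adhera_data_error")
    }
    tibble::as_tibble(tab)[names(spec)]
  })
  out <- structure(tabs, class = "cohort_data")
  check_referential(out)
  out
}

# column name -> storage class ("chr", "int", "dbl", "dttm")
.cdm_columns <- list(
  persons = c(person_id = "chr", birth_year = "int", sex = "chr"),
  encounters = c(person_id = "chr", ward_type = "chr",
                 start = "dttm", end = "dttm"),
  conditions = c(person_id = "chr", system = "chr", code = "chr",
                 onset = "dttm", abatement = "dttm"),
  drug_administrations = c(person_id = "chr", system = "chr", code = "chr",
                           dose_value = "dbl", dose_unit = "chr",
                           administered_at = "dttm"),
  observations = c(person_id = "chr", system = "chr", code = "chr",
                   value_num = "dbl", value_unit = "chr", value_code = "chr",
                   observed_at = "dttm"),
  procedures = c(person_id = "chr", system = "chr", code = "chr",
                 start = "dttm", end = "dttm")
)

empty_table <- function(name) {
  spec <- .cdm_columns[[name]]
  cols <- purrr::map(spec, function(cls) {
    switch(cls,
      chr = character(0),
      int = integer(0),
      dbl = numeric(0),
      dttm = as.POSIXct(character(0), tz = "UTC")
    )
  })
  tibble::as_tibble(cols)
}

check_referential <- function(cohort) {
  known <- cohort$persons$person_id
  if (anyDuplicated(known)) {
    stop_adhera(sprintf("duplicate person_id(s) in persons: %s",
                        paste(unique(known[duplicated(known)]), collapse = ", ")),
                class = "adhera_data_error")
  }
  for (nm in setdiff(names(cohort), "persons")) {
    orphans <- setdiff(unique(cohort[[nm]]$person_id), known)
    if (length(orphans) > 0L) {
      stop_adhera(sprintf(
        "table '%s' references person_id(s) absent from persons: %s",
        nm, paste(orphans, collapse = ", ")),
        class = "adhera_data_error")
    }
  }
  invisible(cohort)
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("<cohort_data>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %6d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

# ---- CSV reading -----------------------------------------------------------

cohort_file_names <- function() {
  paste0(names(.cdm_columns), ".csv")
}

#' Load a cohort from a directory of CSV files
#'
#' Reads the six common-data-model tables (`persons.csv`, `encounters.csv`,
#' `conditions.csv`, `drug_administrations.csv`, `observations.csv`,
#' `procedures.csv`; UTF-8, RFC 4180) and returns a validated
#' [cohort_data()]. Loading is strict: a missing file, a malformed row, an
#' unparseable timestamp, or an event referencing an unknown `person_id`
#' is an error — no silent coercion. Timestamps accept ISO 8601 datetimes
#' (`YYYY-MM-DDTHH:MM:SS`, a space also accepted) or bare dates (interpreted
#' as 00:00).
#'
#' @param directory_path Directory containing the six CSVs.
#' @return A [cohort_data()].
#' @export
load_cohort <- function(directory_path) {
  if (!dir.exists(directory_path)) {
    stop_adhera(sprintf("cohort directory not found: %s", directory_path),
                class = "adhera_io_error")
  }
  tabs <- purrr::imap(.cdm_columns, function(spec, nm) {
    path <- file.path(directory_path, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      stop_adhera(sprintf("missing cohort file: %s", path),
                  class = "adhera_io_error")
    }
    read_cdm_csv(path, spec, nm)
  })
  cohort <- rlang::exec(cohort_data, !!!tabs)
  findings <- validate_cohort(cohort)
  errs <- dplyr::filter(findings, .data$severity == "error")
  if (nrow(errs) > 0L) {
    stop_adhera(paste0(
      "cohort fails validation:\n",
      paste(sprintf("  [%s row %s] %s", errs$table, errs$row, errs$message),
            collapse = "\n")),
      class = "adhera_data_error")
  }
  cohort
}

read_cdm_csv <- function(path, spec, table_name) {
  col_types <- do.call(readr::cols, c(
    purrr::map(spec, function(cls) {
      switch(cls,
        chr = readr::col_character(),
        int = readr::col_integer(),
        dbl = readr::col_double(),
        dttm = readr::col_character() # parsed leniently below
      )
    }),
    list(.default = readr::col_skip())
  ))
  tab <- readr::read_csv(path, col_types = col_types,
                         na = c("", "NA"), progress = FALSE)
  missing <- setdiff(names(spec), names(tab))
  if (length(missing) > 0L) {
    stop_adhera(sprintf("%s: missing column(s) %s",
                        path, paste(missing, collapse = ", ")),
                class = "adhera_io_error")
  }
  probs <- readr::problems(tab)
  if (nrow(probs) > 0L) {
    p <- probs[1L, ]
    stop_adhera(sprintf("%s: malformed value at line %d (%s)",
                        path, p$row + 1L, p$expected),
                class = "adhera_io_error")
  }
  for (col in names(spec)[spec == "dttm"]) {
    raw <- tab[[col]]
    parsed <- parse_timestamp(raw)
    bad <- which(!is.na(raw) & is.na(parsed))
    if (length(bad) > 0L) {
      stop_adhera(sprintf("%s: unparseable timestamp '%s' in column %s, line %d",
                          path, raw[bad[1L]], col, bad[1L] + 1L),
                  class = "adhera_io_error")
    }
    tab[[col]] <- parsed
  }
  tab[names(spec)]
}

# ISO 8601 datetime or bare date -> tz-naive POSIXct (stored as UTC).
parse_timestamp <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  is_date <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  is_dttm <- !is.na(x) &
    grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}(:\\d{2})?$", x)
  out[is_date] <- as.POSIXct(x[is_date], format = "%Y-%m-%d", tz = "UTC")
  if (any(is_dttm)) {
    norm <- sub("T", " ", x[is_dttm], fixed = TRUE)
    norm <- ifelse(nchar(norm) == 16L, paste0(norm, ":00"), norm)
    out[is_dttm] <- as.POSIXct(norm, format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  out
}

# ---- validation ------------------------------------------------------------

#' Validate a cohort and report findings
#'
#' Runs data-quality checks over a [cohort_data()] and returns a
#' machine-readable findings table rather than throwing: interval violations
#' (abatement before onset, encounter/procedure end before start),
#' non-positive doses, observations carrying both or neither of a numeric
#' and coded value, and unknown terminology systems. Never mutates the data.
#'
#' @param cohort A [cohort_data()].
#' @return A tibble with columns `severity` (`"error"`/`"warning"`),
#'   `table`, `row`, `message`; zero rows when the cohort is clean.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_data"))
  f <- list()
  add <- function(severity, table, row, message) {
    f[[length(f) + 1L]] <<- tibble::tibble(
      severity = severity, table = table, row = as.integer(row),
      message = message)
  }
  check_interval <- function(tab, name, start_col, end_col) {
    s <- tab[[start_col]]
    e <- tab[[end_col]]
    bad <- which(!is.na(e) & !is.na(s) & e < s)
    for (i in bad) {
      add("error", name, i,
          sprintf("%s (%s) before %s (%s)", end_col, format(e[i]),
                  start_col, format(s[i])))
    }
  }
  check_systems <- function(tab, name) {
    bad <- which(!is.na(tab$system) & !(tab$system %in% concept_systems()))
    for (i in bad) {
      add("error", name, i,
          sprintf("unknown terminology system '%s'", tab$system[i]))
    }
  }
  check_interval(cohort$encounters, "encounters", "start", "end")
  check_interval(cohort$conditions, "conditions", "onset", "abatement")
  check_interval(cohort$procedures, "procedures", "start", "end")
  for (nm in c("conditions", "drug_administrations", "observations",
               "procedures")) {
    check_systems(cohort[[nm]], nm)
  }
  da <- cohort$drug_administrations
  bad_dose <- which(is.na(da$dose_value) | da$dose_value <= 0)
  for (i in bad_dose) {
    add("error", "drug_administrations", i,
        sprintf("dose_value must be positive, got %s",
                format(da$dose_value[i])))
  }
  obs <- cohort$observations
  n_vals <- (!is.na(obs$value_num)) + (!is.na(obs$value_code))
  for (i in which(n_vals != 1L)) {
    add("error", "observations", i,
        "exactly one of value_num / value_code must be present")
  }
  na_birth <- which(is.na(cohort$persons$birth_year))
  for (i in na_birth) add("warning", "persons", i, "missing birth_year")
  if (length(f) == 0L) {
    return(tibble::tibble(severity = character(0), table = character(0),
                          row = integer(0), message = character(0)))
  }
  dplyr::bind_rows(f)
}

# ---- CSV writing -----------------------------------------------------------

#' Write a cohort to a directory of CSV files
#'
#' Emits the six common-data-model CSVs with their fixed headers.
#' `load_cohort()` on the written directory reproduces an equal
#' [cohort_data()], and the same cohort always produces byte-identical
#' files (timestamps are formatted as `YYYY-MM-DDTHH:MM:SS`, missing values
#' as empty fields).
#'
#' @param cohort A [cohort_data()].
#' @param directory Output directory (created if absent).
#' @return `directory`, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "cohort_data"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(.cdm_columns)) {
    spec <- .cdm_columns[[nm]]
    tab <- cohort[[nm]]
    out <- purrr::imap(as.list(tab), function(col, cn) {
      if (spec[[cn]] == "dttm") format_timestamp(col) else col
    })
    readr::write_csv(tibble::as_tibble(out),
                     file.path(directory, paste0(nm, ".csv")),
                     na = "", progress = FALSE)
  }
  invisible(directory)
}

format_timestamp <- function(x) {
  ifelse(is.na(x), NA_character_, format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
}
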