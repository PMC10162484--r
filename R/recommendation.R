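#' Create a dosage schedule for a drug-administration criterion
#'
#' Describes the regimen a recommendation asks for: a dose per administration
#' event, how many administrations per day, and for how many days. The
#' classic worked example in this package is daily administration of 1 mg
#' dexamethasone for 10 days in critically ill COVID-19 patients requiring
#' oxygen supply.
#'
#' @param dose A [quantity()] per single administration event.
#' @param frequency_per_day Positive integer number of administrations per day.
#' @param duration_days Positive integer course length in days, or
#'   `"unbounded"` / `Inf` for an open-ended regimen.
#' @return An object of class `dosage_spec`.
#' @export
#' @examples
#' dosage_spec(quantity(1, "mg"), frequency_per_day = 1, duration_days = 10)
dosage_spec <- function(dose, frequency_per_day = 1L, duration_days = Inf) {
  if (!inherits(dose, "quantity")) {
    stop_adhera("dosage dose must be a quantity", class = "adhera_schema_error")
  }
  f <- frequency_per_day
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 1 || f != trunc(f)) {
    stop_adhera("frequency_per_day must be a positive integer",
                class = "adhera_schema_error")
  }
  d <- duration_days
  if (identical(d, "unbounded")) d <- Inf
  if (!is.numeric(d) || length(d) != 1L || is.na(d) ||
      (is.finite(d) && (d < 1 || d != trunc(d)))) {
    stop_adhera("duration_days must be a positive integer or \"unbounded\"",
                class = "adhera_schema_error")
  }
  structure(
    list(dose = dose, frequency_per_day = as.integer(f),
         duration_days = as.numeric(d)),
    class = "dosage_spec"
  )
}

criterion_kinds <- function() {
  c("condition", "drug_administration", "observation",
    "procedure_active", "episode_attribute")
}

#' Create a single clinical criterion
#'
#' A criterion is one terminology-coded clinical test: a condition being
#' present on a day, a drug having been administered (optionally according to
#' a [dosage_spec()] schedule), the most recent observation satisfying a
#' comparator, a procedure or therapy episode being active, or the current
#' encounter carrying an episode attribute (e.g. an ICU ward). Criteria are
#' combined with [criterion_group()] into the population and intervention
#' trees of a [recommendation()].
#'
#' @param kind One of `"condition"`, `"drug_administration"`,
#'   `"observation"`, `"procedure_active"`, `"episode_attribute"`.
#' @param concept A [concept_code()] identifying the clinical entity.
#' @param dosage Optional [dosage_spec()]; only valid (and only meaningful)
#'   for `kind = "drug_administration"`.
#' @param comparator Comparator operator for observations; one of
#'   `<, <=, =, >=, >`. Required iff `kind = "observation"`.
#' @param threshold A [quantity()] threshold; required iff
#'   `kind = "observation"`.
#' @param negated Logical; if `TRUE` the criterion's truth value is flipped
#'   (after the closed-world default of `FALSE` for absent data).
#' @return An object of class `criterion`.
#' @export
#' @examples
#' criterion("condition", concept_code("ICD10", "U07.1", "COVID-19"))
#' criterion("observation", concept_code("LOINC", "2708-6", "Oxygen saturation"),
#'           comparator = "<", threshold = quantity(94, "%"))
criterion <- function(kind, concept, dosage = NULL,
                      comparator = NULL, threshold = NULL, negated = FALSE) {
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% criterion_kinds())) {
    stop_adhera(sprintf("unknown criterion kind %s (expected one of %s)",
                        deparse1(kind), paste(criterion_kinds(), collapse = ", ")),
                class = "adhera_schema_error")
  }
  if (!inherits(concept, "concept_code")) {
    stop_adhera("criterion concept must be a concept_code",
                class = "adhera_schema_error")
  }
  if (!is.null(dosage)) {
    if (kind != "drug_administration") {
      stop_adhera("dosage is only allowed on drug_administration criteria",
                  class = "adhera_schema_error")
    }
    if (!inherits(dosage, "dosage_spec")) {
      stop_adhera("dosage must be a dosage_spec", class = "adhera_schema_error")
    }
  }
  if (kind == "observation") {
    if (is.null(comparator) || is.null(threshold)) {
      stop_adhera("observation criteria require a comparator and threshold",
                  class = "adhera_schema_error")
    }
    if (!(comparator %in% comparator_ops())) {
      stop_adhera(sprintf("unknown comparator '%s'", comparator),
                  class = "adhera_schema_error")
    }
    if (!inherits(threshold, "quantity")) {
      stop_adhera("threshold must be a quantity", class = "adhera_schema_error")
    }
  } else if (!is.null(comparator) || !is.null(threshold)) {
    stop_adhera("comparator/threshold are only allowed on observation criteria",
                class = "adhera_schema_error")
  }
  structure(
    list(kind = kind, concept = concept, dosage = dosage,
         comparator = comparator, threshold = threshold,
         negated = isTRUE(negated)),
    class = "criterion"
  )
}

#' Combine criteria with boolean logic
#'
#' Groups [criterion()] objects (or nested groups) under `ALL_OF`
#' (conjunction) or `ANY_OF` (disjunction), optionally negated. The
#' population and intervention parts of a [recommendation()] are each one
#' such tree.
#'
#' @param operator `"ALL_OF"` or `"ANY_OF"`.
#' @param members Non-empty list of `criterion` / `criterion_group` objects.
#' @param negated Logical; flip the group's truth value.
#' @return An object of class `criterion_group`.
#' @export
criterion_group <- function(operator, members, negated = FALSE) {
  if (!is.character(operator) || length(operator) != 1L ||
      !(operator %in% c("ALL_OF", "ANY_OF"))) {
    stop_adhera("operator must be \"ALL_OF\" or \"ANY_OF\"",
                class = "adhera_schema_error")
  }
  if (!is.list(members) || length(members) == 0L) {
    stop_adhera("criterion group must have at least one member",
                class = "adhera_schema_error")
  }
  ok <- vapply(members, function(m)
    inherits(m, "criterion") || inherits(m, "criterion_group"), logical(1))
  if (!all(ok)) {
    stop_adhera("members must be criterion or criterion_group objects",
                class = "adhera_schema_error")
  }
  structure(
    list(operator = operator, members = members, negated = isTRUE(negated)),
    class = "criterion_group"
  )
}

#' Create a guideline recommendation
#'
#' A recommendation is the machine-readable unit the engine executes: content
#' metadata plus the P and I of the PICO decomposition — a population
#' criterion tree ("who does this apply to") and an intervention criterion
#' tree ("what should be done"). Comparison and outcome elements, where
#' present in a source document, are not used by the evaluation semantics.
#'
#' @param id Stable recommendation identifier shared across versions.
#' @param title Human-readable title.
#' @param version Version label (free-form string).
#' @param valid_from `Date` (or `"YYYY-MM-DD"` string) on which this version
#'   becomes valid; the boundary is inclusive.
#' @param population,intervention [criterion_group()] trees.
#' @return An object of class `recommendation`.
#' @export
recommendation <- function(id, title, version, valid_from,
                           population, intervention) {
  for (nm in c("id", "title", "version")) {
    v <- get(nm)
    if (!is.character(v) || length(v) != 1L || is.na(v) || !nzchar(v)) {
      stop_adhera(sprintf("recommendation %s must be a non-empty string", nm),
                  class = "adhera_schema_error")
    }
  }
  valid_from <- as_calendar_date(valid_from, "valid_from")
  if (!inherits(population, "criterion_group")) {
    stop_adhera("population must be a criterion_group",
                class = "adhera_schema_error", path = "/population")
  }
  if (!inherits(intervention, "criterion_group")) {
    stop_adhera("intervention must be a criterion_group",
                class = "adhera_schema_error", path = "/intervention")
  }
  structure(
    list(id = id, title = title, version = version, valid_from = valid_from,
         population = population, intervention = intervention),
    class = "recommendation"
  )
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("<recommendation> %s (version %s, valid from %s)\n",
              x$id, x$version, format(x$valid_from)))
  cat("  title:", x$title, "\n")
  cat(sprintf("  population:   %d leaf criteria\n", n_leaves(x$population)))
  cat(sprintf("  intervention: %d leaf criteria\n", n_leaves(x$intervention)))
  invisible(x)
}

n_leaves <- function(node) {
  if (inherits(node, "criterion")) return(1L)
  sum(vapply(node$members, n_leaves, integer(1)))
}

as_calendar_date <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  if (is.character(x) && length(x) == 1L &&
      grepl("^\\d{4}-\\d{2}-\\d{2}$", x)) {
    d <- as.Date(x, format = "%Y-%m-%d")
    if (!is.na(d)) return(d)
  }
  stop_adhera(sprintf("%s must be an ISO 8601 date (YYYY-MM-DD), got %s",
                      what, deparse1(x)),
              class = "adhera_schema_error")
}

# ---- JSON parsing ----------------------------------------------------------

#' Parse a recommendation document
#'
#' Reads the declarative JSON dialect in which recommendations are exchanged
#' (schema published at `system.file("schema", "recommendation.schema.json",
#' package = "adhera")`). Validation is total: the document either yields a
#' fully validated [recommendation()] or a structured error naming the JSON
#' path of the offending element; no partially constructed object escapes.
#' Unknown top-level fields (including PICO `comparison` and `outcome`
#' elements) are ignored with a warning.
#'
#' @param document JSON text (a single string), or a path to a `.json` file.
#' @return A [recommendation()].
#' @seealso [serialize_recommendation()] for the inverse,
#'   [select_version()] for picking among versions.
#' @export
#' @examples
#' path <- system.file("extdata", "recommendation-dexamethasone.json",
#'                     package = "adhera")
#' rec <- parse_recommendation(path)
#' rec
parse_recommendation <- function(document) {
  if (length(document) == 1L && !grepl("[{\\[]", substr(document, 1L, 1L)) &&
      file.exists(document)) {
    document <- paste(readLines(document, warn = FALSE, encoding = "UTF-8"),
                      collapse = "\n")
  }
  doc <- tryCatch(
    jsonlite::fromJSON(document, simplifyVector = FALSE),
    error = function(e) {
      stop_adhera(paste0("invalid JSON: ", conditionMessage(e)),
                  class = "adhera_schema_error", path = "/")
    }
  )
  if (!is.list(doc) || is.null(names(doc))) {
    stop_adhera("recommendation document must be a JSON object",
                class = "adhera_schema_error", path = "/")
  }
  known <- c("id", "title", "version", "valid_from", "population",
             "intervention", "comparison", "outcome")
  extra <- setdiff(names(doc), known)
  if (length(extra) > 0L) {
    warning(sprintf("ignoring unknown top-level field(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  for (f in c("id", "title", "version", "valid_from", "population",
              "intervention")) {
    if (is.null(doc[[f]])) {
      stop_adhera(sprintf("missing required field at /%s", f),
                  class = "adhera_schema_error", path = paste0("/", f))
    }
  }
  recommendation(
    id = as_scalar_string(doc$id, "/id"),
    title = as_scalar_string(doc$title, "/title"),
    version = as_scalar_string(doc$version, "/version"),
    valid_from = located(as_calendar_date(doc$valid_from, "valid_from"),
                         "/valid_from"),
    population = parse_node(doc$population, "/population", top = TRUE),
    intervention = parse_node(doc$intervention, "/intervention", top = TRUE)
  )
}

# Re-raise validation errors lacking a JSON path with one attached.
located <- function(expr, path) {
  withCallingHandlers(expr, adhera_error = function(e) {
    if (is.null(e$path)) {
      stop_adhera(paste0(conditionMessage(e), " at ", path),
                  class = "adhera_schema_error", path = path)
    }
  })
}

as_scalar_string <- function(x, path) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop_adhera(sprintf("expected a non-empty string at %s", path),
                class = "adhera_schema_error", path = path)
  }
  x
}

parse_node <- function(node, path, top = FALSE) {
  if (!is.list(node)) {
    stop_adhera(sprintf("expected an object at %s", path),
                class = "adhera_schema_error", path = path)
  }
  type <- node$type
  if (is.null(type)) {
    type <- if (!is.null(node$operator)) "combination" else "criterion"
  }
  if (identical(type, "combination")) {
    if (is.null(node$operator)) {
      stop_adhera(sprintf("missing operator at %s/operator", path),
                  class = "adhera_schema_error", path = paste0(path, "/operator"))
    }
    members <- node$members
    if (is.null(members) || !is.list(members) || length(members) == 0L) {
      stop_adhera(sprintf("criterion group at %s must have non-empty members", path),
                  class = "adhera_schema_error", path = paste0(path, "/members"))
    }
    parsed <- lapply(seq_along(members), function(i) {
      parse_node(members[[i]], sprintf("%s/members/%d", path, i - 1L))
    })
    located(
      criterion_group(as_scalar_string(node$operator, paste0(path, "/operator")),
                      parsed, negated = isTRUE(node$negated)),
      path
    )
  } else if (identical(type, "criterion")) {
    if (top) {
      stop_adhera(
        sprintf("%s must be a criterion combination (wrap single criteria in ALL_OF)",
                path),
        class = "adhera_schema_error", path = path
      )
    }
    located(parse_leaf(node, path), path)
  } else {
    stop_adhera(sprintf("unknown node type '%s' at %s", type, path),
                class = "adhera_schema_error", path = paste0(path, "/type"))
  }
}

parse_leaf <- function(node, path) {
  if (is.null(node$kind)) {
    stop_adhera(sprintf("missing criterion kind at %s/kind", path),
                class = "adhera_schema_error", path = paste0(path, "/kind"))
  }
  concept <- parse_concept(node$concept, paste0(path, "/concept"))
  dosage <- NULL
  if (!is.null(node$dosage)) {
    dpath <- paste0(path, "/dosage")
    d <- node$dosage
    dosage <- located(
      dosage_spec(
        dose = parse_quantity(d$dose, paste0(dpath, "/dose")),
        frequency_per_day = d$frequency_per_day %||% 1L,
        duration_days = d$duration_days %||% Inf
      ),
      dpath
    )
  }
  comparator <- NULL
  threshold <- NULL
  if (!is.null(node$comparator)) {
    cpath <- paste0(path, "/comparator")
    comparator <- as_scalar_string(node$comparator$op %||% node$comparator,
                                   paste0(cpath, "/op"))
    threshold <- parse_quantity(node$comparator$threshold %||% node$threshold,
                                paste0(cpath, "/threshold"))
  }
  criterion(
    kind = as_scalar_string(node$kind, paste0(path, "/kind")),
    concept = concept, dosage = dosage,
    comparator = comparator, threshold = threshold,
    negated = isTRUE(node$negated)
  )
}

parse_concept <- function(x, path) {
  if (!is.list(x) || is.null(x$system) || is.null(x$code)) {
    stop_adhera(sprintf("expected {system, code} object at %s", path),
                class = "adhera_schema_error", path = path)
  }
  located(
    concept_code(as_scalar_string(x$system, paste0(path, "/system")),
                 as_scalar_string(x$code, paste0(path, "/code")),
                 display = x$display),
    path
  )
}

parse_quantity <- function(x, path) {
  if (!is.list(x) || is.null(x$value) || is.null(x$unit)) {
    stop_adhera(sprintf("expected {value, unit} object at %s", path),
                class = "adhera_schema_error", path = path)
  }
  unit <- if (is.character(x$unit)) concept_code("UCUM", x$unit) else
    parse_concept(x$unit, paste0(path, "/unit"))
  located(quantity(as.numeric(x$value), unit), path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- JSON serialization ----------------------------------------------------

#' Serialize a recommendation to JSON
#'
#' The inverse of [parse_recommendation()]: the emitted document re-parses to
#' a structurally equal recommendation, and serializing the same object twice
#' yields byte-identical output (deterministic key order). This is the
#' content-only update pathway: exchanging recommendation documents changes
#' the engine's behaviour with no code change.
#'
#' @param rec A [recommendation()].
#' @param path Optional file path; if given, the JSON is also written there.
#' @return JSON text, invisibly when `path` is given.
#' @export
serialize_recommendation <- function(rec, path = NULL) {
  stopifnot(inherits(rec, "recommendation"))
  doc <- list(
    id = rec$id, title = rec$title, version = rec$version,
    valid_from = format(rec$valid_from, "%Y-%m-%d"),
    population = node_to_list(rec$population),
    intervention = node_to_list(rec$intervention)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  json <- paste0(as.character(json), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", json), path, useBytes = TRUE)
    return(invisible(json))
  }
  json
}

node_to_list <- function(node) {
  if (inherits(node, "criterion_group")) {
    list(type = "combination", operator = node$operator,
         negated = node$negated,
         members = lapply(node$members, node_to_list))
  } else {
    out <- list(type = "criterion", kind = node$kind,
                concept = concept_to_list(node$concept),
                negated = node$negated)
    if (!is.null(node$dosage)) {
      d <- node$dosage
      out$dosage <- list(
        dose = quantity_to_list(d$dose),
        frequency_per_day = d$frequency_per_day,
        duration_days = if (is.finite(d$duration_days)) d$duration_days
                        else "unbounded"
      )
    }
    if (!is.null(node$comparator)) {
      out$comparator <- list(op = node$comparator,
                             threshold = quantity_to_list(node$threshold))
    }
    out
  }
}

concept_to_list <- function(x) {
  out <- list(system = x$system, code = x$code)
  if (!is.null(x$display)) out$display <- x$display
  out
}

quantity_to_list <- function(q) {
  list(value = q$value, unit = concept_to_list(q$unit))
}

# ---- versioning ------------------------------------------------------------

#' Select the recommendation version valid on a date
#'
#' Guideline content changes as evidence accrues; versions of one
#' recommendation share an `id` and differ in `valid_from`. This returns the
#' version with the latest `valid_from` on or before `on_date` (the boundary
#' is inclusive: a version released on a day is valid that day), or `NULL`
#' if no version is yet valid. The result is independent of the input
#' ordering.
#'
#' @param versions List of [recommendation()] objects sharing one `id`.
#' @param on_date `Date` or `"YYYY-MM-DD"`.
#' @return A [recommendation()] or `NULL`.
#' @export
select_version <- function(versions, on_date) {
  stopifnot(is.list(versions), length(versions) > 0L)
  ok <- vapply(versions, inherits, logical(1), what = "recommendation")
  if (!all(ok)) {
    stop_adhera("versions must be recommendation objects",
                class = "adhera_schema_error")
  }
  ids <- vapply(versions, function(r) r$id, character(1))
  if (length(unique(ids)) != 1L) {
    stop_adhera(sprintf("versions carry mixed ids: %s",
                        paste(unique(ids), collapse = ", ")),
                class = "adhera_version_error")
  }
  froms <- as.Date(vapply(versions, function(r) format(r$valid_from),
                          character(1)))
  if (anyDuplicated(froms)) {
    stop_adhera("valid_from dates must be strictly ordered across versions",
                class = "adhera_version_error")
  }
  on_date <- as_calendar_date(on_date, "on_date")
  eligible <- which(froms <= on_date)
  if (length(eligible) == 0L) return(NULL)
  versions[[eligible[which.max(froms[eligible])]]]
}
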