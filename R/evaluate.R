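#' Define a day-granular evaluation window
#'
#' All evaluation is at calendar-day granularity: recommendation semantics
#' ("daily administration") and cohort time series are day-based. The window
#' is the closed date range over which patient-days are evaluated; open-ended
#' clinical intervals are treated as extending to its end.
#'
#' @param start_date,end_date `Date` or `"YYYY-MM-DD"`; `start_date` must not
#'   be after `end_date`.
#' @return An object of class `evaluation_window`.
#' @export
#' @examples
#' evaluation_window("2020-03-01", "2021-05-31")
evaluation_window <- function(start_date, end_date) {
  start_date <- as_calendar_date(start_date, "start_date")
  end_date <- as_calendar_date(end_date, "end_date")
  if (start_date > end_date) {
    stop_adhera("start_date must be on or before end_date",
                class = "adhera_schema_error")
  }
  structure(list(start_date = start_date, end_date = end_date),
            class = "evaluation_window")
}

#' @export
print.evaluation_window <- function(x, ...) {
  cat(sprintf("<evaluation_window> %s .. %s (%d days)\n",
              format(x$start_date), format(x$end_date),
              as.integer(x$end_date - x$start_date) + 1L))
  invisible(x)
}

window_days <- function(window) {
  seq(window$start_date, window$end_date, by = "day")
}

# ---- compilation -----------------------------------------------------------

#' Compile a recommendation into an executable rule plan
#'
#' Turns the declarative criterion trees of a [recommendation()] into an
#' executable event-condition-action plan: every leaf concept is resolved
#' through the [codemap()] to the local codes used in patient data, and the
#' tree shape is preserved with a JSON-pointer path attached to each leaf
#' (used in error messages and in the per-criterion audit output).
#' Compilation is pure — it touches no patient data — and deterministic:
#' compiling the same inputs twice yields equal plans.
#'
#' @param rec A [recommendation()].
#' @param map A [codemap()]; defaults to the identity mapping.
#' @param dose_tolerance Relative tolerance on a day's total administered
#'   dose when checking a [dosage_spec()] (default 0.10; clinical rounding
#'   makes exact equality meaningless).
#' @return An object of class `executable_plan`.
#' @export
compile_plan <- function(rec, map = identity_codemap(), dose_tolerance = 0.1) {
  stopifnot(inherits(rec, "recommendation"), inherits(map, "codemap"))
  if (!is.numeric(dose_tolerance) || dose_tolerance < 0) {
    stop_adhera("dose_tolerance must be a non-negative number",
                class = "adhera_schema_error")
  }
  structure(
    list(
      id = rec$id, version = rec$version, valid_from = rec$valid_from,
      population = compile_node(rec$population, map, "/population"),
      intervention = compile_node(rec$intervention, map, "/intervention"),
      dose_tolerance = as.numeric(dose_tolerance)
    ),
    class = "executable_plan"
  )
}

compile_node <- function(node, map, path) {
  if (inherits(node, "criterion_group")) {
    members <- lapply(seq_along(node$members), function(i) {
      compile_node(node$members[[i]], map,
                   sprintf("%s/members/%d", path, i - 1L))
    })
    structure(list(operator = node$operator, members = members,
                   negated = node$negated, path = path),
              class = "compiled_group")
  } else {
    local_codes <- tryCatch(
      resolve_codes(map, node$concept),
      adhera_terminology_error = function(e) {
        stop_adhera(sprintf("cannot compile criterion at %s: %s",
                            path, conditionMessage(e)),
                    class = "adhera_compile_error", path = path)
      }
    )
    structure(list(criterion = node, local_codes = local_codes, path = path),
              class = "compiled_leaf")
  }
}

#' @export
print.executable_plan <- function(x, ...) {
  cat(sprintf("<executable_plan> %s (version %s)\n", x$id, x$version))
  cat(sprintf("  population:   %d leaf rule(s)\n",
              length(plan_leaves(x$population))))
  cat(sprintf("  intervention: %d leaf rule(s)\n",
              length(plan_leaves(x$intervention))))
  cat(sprintf("  dose tolerance: %.0f%%\n", 100 * x$dose_tolerance))
  invisible(x)
}

plan_leaves <- function(node) {
  if (inherits(node, "compiled_leaf")) return(list(node))
  purrr::flatten(purrr::map(node$members, plan_leaves))
}

# ---- vectorised day-level rule execution -----------------------------------
#
# The engine evaluates each leaf once over the full person x day grid of the
# window, as a logical vector indexed by (person position, day position).
# Interval events are expanded to the day indices they cover under the
# half-open [start, end) convention; absent data yields FALSE (closed world)
# before any negation is applied.

day_index <- function(t, origin_day) {
  as.integer(floor(as.numeric(t) / 86400)) - as.integer(origin_day)
}

new_grid <- function(person_ids, window) {
  days <- window_days(window)
  list(
    person_ids = person_ids,
    days = days,
    n_person = length(person_ids),
    n_day = length(days),
    origin = as.integer(days[1L])
  )
}

grid_false <- function(grid) {
  matrix(FALSE, nrow = grid$n_day, ncol = grid$n_person)
}

# Mark TRUE on day range [from_idx, to_idx] (0-based day offsets, clipped).
mark_range <- function(mat, grid, person, from_idx, to_idx) {
  p <- match(person, grid$person_ids)
  keep <- !is.na(p)
  for (k in which(keep)) {
    a <- max(from_idx[k], 0L) + 1L
    b <- min(to_idx[k], grid$n_day - 1L) + 1L
    if (a <= b) mat[a:b, p[k]] <- TRUE
  }
  mat
}

match_codes <- function(tab, local_codes) {
  keys <- vapply(local_codes, concept_key, character(1))
  paste(tab$system, tab$code, sep = "|") %in% keys
}

# Day coverage of half-open intervals: first covered day floor(start/1d),
# last covered day floor((end - 1s)/1d); open end extends to the window end.
interval_truth <- function(grid, person, start, end) {
  mat <- grid_false(grid)
  if (length(person) == 0L) return(mat)
  from <- day_index(start, grid$origin)
  to <- ifelse(is.na(end), grid$n_day - 1L, day_index(end - 1, grid$origin))
  mark_range(mat, grid, person, from, pmax(to, -1L))
}

leaf_truth <- function(leaf, cohort, grid, dose_tolerance) {
  crit <- leaf$criterion
  out <- switch(crit$kind,
    condition = {
      tab <- cohort$conditions
      tab <- tab[match_codes(tab, leaf$local_codes), , drop = FALSE]
      interval_truth(grid, tab$person_id, tab$onset, tab$abatement)
    },
    procedure_active = {
      tab <- cohort$procedures
      tab <- tab[match_codes(tab, leaf$local_codes), , drop = FALSE]
      interval_truth(grid, tab$person_id, tab$start, tab$end)
    },
    episode_attribute = {
      tab <- cohort$encounters
      codes <- vapply(leaf$local_codes, function(c) c$code, character(1))
      tab <- tab[tab$ward_type %in% codes, , drop = FALSE]
      interval_truth(grid, tab$person_id, tab$start, tab$end)
    },
    drug_administration = {
      if (is.null(crit$dosage)) {
        tab <- cohort$drug_administrations
        tab <- tab[match_codes(tab, leaf$local_codes), , drop = FALSE]
        d <- day_index(tab$administered_at, grid$origin)
        mark_range(grid_false(grid), grid, tab$person_id, d, d)
      } else {
        dosage_truth(leaf, cohort, grid, dose_tolerance)
      }
    },
    observation = observation_truth(leaf, cohort, grid),
    stop_adhera(sprintf("unsupported criterion kind '%s'", crit$kind),
                class = "adhera_schema_error")
  )
  if (crit$negated) !out else out
}

observation_truth <- function(leaf, cohort, grid) {
  crit <- leaf$criterion
  mat <- grid_false(grid)
  tab <- cohort$observations
  tab <- tab[match_codes(tab, leaf$local_codes), , drop = FALSE]
  if (nrow(tab) == 0L) return(mat)
  # End-of-day cutoffs: the most recent matching observation at or before
  # the day decides; a coded (non-numeric) value never satisfies a
  # numeric comparator.
  day_ends <- (as.numeric(grid$origin) + seq_len(grid$n_day)) * 86400
  for (p in unique(tab$person_id)) {
    pc <- match(p, grid$person_ids)
    if (is.na(pc)) next
    rows <- tab[tab$person_id == p, , drop = FALSE]
    ord <- order(rows$observed_at)
    times <- as.numeric(rows$observed_at)[ord]
    sat <- vapply(ord, function(i) {
      if (is.na(rows$value_num[i]) || is.na(rows$value_unit[i])) return(FALSE)
      isTRUE(compare_quantity(rows$value_num[i], rows$value_unit[i],
                              crit$comparator, crit$threshold))
    }, logical(1))
    idx <- findInterval(day_ends - 0.5, times)
    mat[, pc] <- idx > 0L & sat[pmax(idx, 1L)]
  }
  mat
}

# Course-based dosage rule. A day is fulfilled iff it lies inside a
# conformant course: a fresh course start s (no matching administration in
# the preceding duration_days for bounded courses, none on the previous day
# for unbounded ones) with every day from s through the query day carrying
# exactly frequency_per_day matching administrations whose daily total dose
# is within the relative tolerance, and the query day within the course
# length. Days after a completed course are not fulfilled; a patient
# mid-course counts as fulfilled (ongoing-adherent).
dosage_truth <- function(leaf, cohort, grid, dose_tolerance) {
  crit <- leaf$criterion
  spec <- crit$dosage
  mat <- grid_false(grid)
  tab <- cohort$drug_administrations
  tab <- tab[match_codes(tab, leaf$local_codes), , drop = FALSE]
  if (nrow(tab) == 0L) return(mat)
  target_unit <- spec$dose$unit$code
  daily_target <- spec$dose$value * spec$frequency_per_day
  dur <- spec$duration_days
  tab$day <- day_index(tab$administered_at, grid$origin)
  tab$dose_norm <- ucum_convert(tab$dose_value, tab$dose_unit, target_unit)
  for (p in unique(tab$person_id)) {
    pc <- match(p, grid$person_ids)
    if (is.na(pc)) next
    rows <- tab[tab$person_id == p, , drop = FALSE]
    counts <- tapply(rows$dose_norm, rows$day, length)
    totals <- tapply(rows$dose_norm, rows$day, sum)
    admin_days <- as.integer(names(counts))
    conformant <- admin_days[
      counts == spec$frequency_per_day &
        abs(totals - daily_target) <= dose_tolerance * daily_target
    ]
    washout <- if (is.finite(dur)) dur else 1
    starts <- admin_days[vapply(admin_days, function(s) {
      !any(admin_days >= s - washout & admin_days <= s - 1)
    }, logical(1))]
    for (s in starts) {
      # longest conformant streak from s
      m <- 0L
      while ((s + m) %in% conformant) m <- m + 1L
      if (m == 0L) next
      last <- s + min(m, if (is.finite(dur)) dur else Inf) - 1L
      a <- max(s, 0L) + 1L
      b <- min(last, grid$n_day - 1L) + 1L
      if (a <= b) mat[a:b, pc] <- TRUE
    }
  }
  mat
}

node_truth <- function(node, cohort, grid, dose_tolerance, collect = NULL) {
  if (inherits(node, "compiled_leaf")) {
    val <- leaf_truth(node, cohort, grid, dose_tolerance)
    if (!is.null(collect)) collect(node$path, val)
    return(val)
  }
  vals <- lapply(node$members, node_truth, cohort = cohort, grid = grid,
                 dose_tolerance = dose_tolerance, collect = collect)
  out <- purrr::reduce(vals, if (node$operator == "ALL_OF") `&` else `|`)
  if (node$negated) !out else out
}

encounter_gate <- function(cohort, grid) {
  enc <- cohort$encounters
  interval_truth(grid, enc$person_id, enc$start, enc$end)
}

# ---- public evaluation surface ---------------------------------------------

#' Evaluate a single criterion for one patient-day
#'
#' Exposes the engine's leaf semantics directly: conditions and procedures
#' are true on days covered by a matching half-open interval; an unscheduled
#' drug criterion is true on days with at least one matching administration;
#' a scheduled drug criterion follows the course semantics of
#' [evaluate_dosage()]; an observation criterion is true when the most
#' recent matching observation at or before the day satisfies the comparator
#' after unit normalisation. Absent data is false (closed world); `negated`
#' then flips the result.
#'
#' @param crit A [criterion()].
#' @param cohort A [cohort_data()].
#' @param person_id Person identifier present in the cohort.
#' @param date `Date` or `"YYYY-MM-DD"`.
#' @param map A [codemap()] (default identity).
#' @param dose_tolerance Relative daily-dose tolerance (default 0.10).
#' @return A single logical.
#' @export
evaluate_criterion <- function(crit, cohort, person_id, date,
                               map = identity_codemap(),
                               dose_tolerance = 0.1) {
  stopifnot(inherits(crit, "criterion"))
  check_person(cohort, person_id)
  date <- as_calendar_date(date, "date")
  leaf <- compile_node(crit, map, "/criterion")
  grid <- new_grid(person_id, evaluation_window(date, date))
  as.logical(leaf_truth(leaf, cohort, grid, dose_tolerance))[1L]
}

#' Evaluate a dosage-scheduled drug criterion for one patient-day
#'
#' @inheritParams evaluate_criterion
#' @param crit A [criterion()] of kind `drug_administration` carrying a
#'   [dosage_spec()].
#' @return A single logical.
#' @export
evaluate_dosage <- function(crit, cohort, person_id, date,
                            map = identity_codemap(), dose_tolerance = 0.1) {
  stopifnot(inherits(crit, "criterion"))
  if (is.null(crit$dosage)) {
    stop_adhera("evaluate_dosage requires a criterion with a dosage_spec",
                class = "adhera_schema_error")
  }
  evaluate_criterion(crit, cohort, person_id, date, map, dose_tolerance)
}

#' Evaluate a criterion combination for one patient-day
#'
#' `ALL_OF` is the conjunction and `ANY_OF` the disjunction of the members'
#' results; `negated` flips the group. Member order never affects the
#' result.
#'
#' @param node A [criterion_group()].
#' @inheritParams evaluate_criterion
#' @return A single logical.
#' @export
evaluate_combination <- function(node, cohort, person_id, date,
                                 map = identity_codemap(),
                                 dose_tolerance = 0.1) {
  stopifnot(inherits(node, "criterion_group"))
  check_person(cohort, person_id)
  date <- as_calendar_date(date, "date")
  compiled <- compile_node(node, map, "/combination")
  grid <- new_grid(person_id, evaluation_window(date, date))
  as.logical(node_truth(compiled, cohort, grid, dose_tolerance))[1L]
}

check_person <- function(cohort, person_id) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (!(person_id %in% cohort$persons$person_id)) {
    stop_adhera(sprintf("unknown person_id '%s'", person_id),
                class = "adhera_data_error")
  }
  invisible(TRUE)
}

#' Evaluate a recommendation for one patient over a window
#'
#' Produces one row per day in the window. A day's
#' `population_applicable` requires both an active encounter covering the
#' day (patients not admitted are not applicable) and the population
#' criterion tree; `adherent` is `population_applicable AND
#' intervention_fulfilled` by construction.
#'
#' @param plan An [compile_plan()] result.
#' @param cohort A [cohort_data()].
#' @param person_id Person identifier present in the cohort.
#' @param window An [evaluation_window()].
#' @return A tibble with columns `person_id`, `date`,
#'   `population_applicable`, `intervention_fulfilled`, `adherent`.
#' @export
evaluate_patient <- function(plan, cohort, person_id, window) {
  stopifnot(inherits(plan, "executable_plan"),
            inherits(window, "evaluation_window"))
  check_person(cohort, person_id)
  grid <- new_grid(person_id, window)
  day_results_for_grid(plan, cohort, grid)
}

day_results_for_grid <- function(plan, cohort, grid, collect = NULL) {
  pop <- node_truth(plan$population, cohort, grid, plan$dose_tolerance,
                    collect = collect)
  intv <- node_truth(plan$intervention, cohort, grid, plan$dose_tolerance,
                     collect = collect)
  admitted <- encounter_gate(cohort, grid)
  applicable <- admitted & pop
  tibble::tibble(
    person_id = rep(grid$person_ids, each = grid$n_day),
    date = rep(grid$days, times = grid$n_person),
    population_applicable = as.vector(applicable),
    intervention_fulfilled = as.vector(intv),
    adherent = as.vector(applicable & intv)
  )
}

#' Evaluate a recommendation over a whole cohort
#'
#' Runs the compiled plan for every person in the cohort over every day of
#' the window and aggregates the per-day results into a cohort time series:
#' the number of patients to which the recommendation is applicable, the
#' number treated according to it, and the adherent fraction (undefined —
#' `NA` — on days with no applicable patient). Evaluation is deterministic
#' and invariant to patient processing order.
#'
#' @inheritParams evaluate_patient
#' @param keep_leaf_results If `TRUE` (default), per-criterion truth values
#'   are retained for every patient-day, keyed by the criterion's
#'   JSON-pointer path — the audit trail from which every day-level verdict
#'   can be reconstructed by re-applying the boolean tree.
#' @return An object of class `cohort_evaluation`: a list with elements
#'   `series` (tibble: `date`, `n_applicable`, `n_adherent`, `fraction`),
#'   `day_results` (one row per person-day), `leaf_results` (or `NULL`),
#'   `plan`, and `window`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
evaluate_cohort <- function(plan, cohort, window, keep_leaf_results = TRUE) {
  stopifnot(inherits(plan, "executable_plan"),
            inherits(cohort, "cohort_data"),
            inherits(window, "evaluation_window"))
  grid <- new_grid(cohort$persons$person_id, window)
  leaf_store <- new.env(parent = emptyenv())
  collect <- if (keep_leaf_results) {
    function(path, val) assign(path, val, envir = leaf_store)
  }
  day_results <- day_results_for_grid(plan, cohort, grid, collect = collect)
  series <- day_results |>
    dplyr::group_by(date = .data$date) |>
    dplyr::summarise(
      n_applicable = sum(.data$population_applicable),
      n_adherent = sum(.data$adherent),
      .groups = "drop"
    ) |>
    # every window day gets a row, even for an empty cohort
    dplyr::right_join(tibble::tibble(date = grid$days), by = "date") |>
    dplyr::arrange(.data$date) |>
    dplyr::mutate(
      n_applicable = dplyr::coalesce(.data$n_applicable, 0L),
      n_adherent = dplyr::coalesce(.data$n_adherent, 0L),
      fraction = dplyr::if_else(.data$n_applicable > 0,
                                .data$n_adherent / .data$n_applicable,
                                NA_real_)
    )
  leaf_results <- NULL
  if (keep_leaf_results) {
    paths <- sort(ls(leaf_store))
    leaf_results <- purrr::map_dfr(paths, function(p) {
      tibble::tibble(
        person_id = rep(grid$person_ids, each = grid$n_day),
        date = rep(grid$days, times = grid$n_person),
        criterion_path = p,
        result = as.vector(get(p, envir = leaf_store))
      )
    })
  }
  structure(
    list(series = series, day_results = day_results,
         leaf_results = leaf_results, plan = plan, window = window),
    class = "cohort_evaluation"
  )
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf("<cohort_evaluation> %s (version %s), %s .. %s\n",
              x$plan$id, x$plan$version,
              format(x$window$start_date), format(x$window$end_date)))
  n_app <- sum(x$series$n_applicable)
  n_adh <- sum(x$series$n_adherent)
  cat(sprintf("  %d patient-days applicable, %d adherent (%.1f%%)\n",
              n_app, n_adh, if (n_app > 0) 100 * n_adh / n_app else NA_real_))
  invisible(x)
}
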