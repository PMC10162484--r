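#' Reference brute-force cohort evaluator
#'
#' An independent, deliberately naive implementation of the evaluation
#' semantics used to validate the compiled rule engine: it enumerates every
#' (patient, day, leaf) triple directly from the recommendation — no rule
#' compilation, no vectorisation, no shared code with the execution path —
#' resolving codes through the [codemap()] at each leaf and recursing over
#' the criterion trees with plain loops. Intended for small instances
#' (tens of patients, tens of days); the compiled engine
#' ([evaluate_cohort()]) must agree with it exactly.
#'
#' @param rec A [recommendation()].
#' @param cohort A [cohort_data()].
#' @param window An [evaluation_window()].
#' @param map A [codemap()] (default identity).
#' @param dose_tolerance Relative daily-dose tolerance (default 0.10).
#' @return A list with `day_results` and `series` tibbles shaped like the
#'   corresponding elements of a [evaluate_cohort()] result.
#' @export
evaluate_cohort_naive <- function(rec, cohort, window,
                                  map = identity_codemap(),
                                  dose_tolerance = 0.1) {
  stopifnot(inherits(rec, "recommendation"),
            inherits(cohort, "cohort_data"),
            inherits(window, "evaluation_window"))
  days <- window_days(window)
  persons <- cohort$persons$person_id
  # plain data frames: the naive path uses base subsetting only
  cohort_df <- structure(lapply(unclass(cohort), as.data.frame),
                         class = "cohort_data")
  n_total <- length(persons) * length(days)
  out_person <- character(n_total)
  out_date <- rep(days[1L], n_total)
  out_pop <- logical(n_total)
  out_int <- logical(n_total)
  k <- 0L
  for (p in persons) {
    for (d in as.list(days)) {
      admitted <- naive_any_interval(cohort_df$encounters, "start", "end",
                                     cohort_df$encounters$person_id == p,
                                     d, window)
      pop <- naive_node(rec$population, cohort_df, p, d, map,
                        dose_tolerance, window)
      intv <- naive_node(rec$intervention, cohort_df, p, d, map,
                         dose_tolerance, window)
      k <- k + 1L
      out_person[k] <- p
      out_date[k] <- d
      out_pop[k] <- admitted && pop
      out_int[k] <- intv
    }
  }
  day_results <- tibble::tibble(
    person_id = out_person, date = out_date,
    population_applicable = out_pop,
    intervention_fulfilled = out_int,
    adherent = out_pop & out_int
  )
  series <- day_results |>
    dplyr::group_by(date = .data$date) |>
    dplyr::summarise(n_applicable = sum(.data$population_applicable),
                     n_adherent = sum(.data$adherent), .groups = "drop") |>
    dplyr::mutate(fraction = dplyr::if_else(
      .data$n_applicable > 0, .data$n_adherent / .data$n_applicable,
      NA_real_))
  list(day_results = day_results, series = series)
}

naive_node <- function(node, cohort, p, d, map, tol, window) {
  if (inherits(node, "criterion_group")) {
    vals <- vapply(node$members, naive_node, logical(1),
                   cohort = cohort, p = p, d = d, map = map, tol = tol,
                   window = window)
    out <- if (node$operator == "ALL_OF") all(vals) else any(vals)
    if (node$negated) !out else out
  } else {
    naive_leaf(node, cohort, p, d, map, tol, window)
  }
}

naive_leaf <- function(crit, cohort, p, d, map, tol, window) {
  locals <- resolve_codes(map, crit$concept)
  keys <- vapply(locals, concept_key, character(1))
  out <- switch(crit$kind,
    condition = {
      tab <- cohort$conditions
      sel <- tab$person_id == p &
        paste(tab$system, tab$code, sep = "|") %in% keys
      naive_any_interval(tab, "onset", "abatement", sel, d, window)
    },
    procedure_active = {
      tab <- cohort$procedures
      sel <- tab$person_id == p &
        paste(tab$system, tab$code, sep = "|") %in% keys
      naive_any_interval(tab, "start", "end", sel, d, window)
    },
    episode_attribute = {
      tab <- cohort$encounters
      codes <- vapply(locals, function(x) x$code, character(1))
      sel <- tab$person_id == p & tab$ward_type %in% codes
      naive_any_interval(tab, "start", "end", sel, d, window)
    },
    drug_administration = {
      if (is.null(crit$dosage)) {
        tab <- cohort$drug_administrations
        sel <- tab$person_id == p &
          paste(tab$system, tab$code, sep = "|") %in% keys
        any(sel & naive_on_day(tab$administered_at, d))
      } else {
        naive_dosage(crit, cohort, p, d, keys, tol)
      }
    },
    observation = {
      tab <- cohort$observations
      sel <- tab$person_id == p &
        paste(tab$system, tab$code, sep = "|") %in% keys &
        tab$observed_at < day_start(d) + 86400
      if (!any(sel)) FALSE else {
        tab <- tab[sel, , drop = FALSE]
        tn <- as.numeric(tab$observed_at)
        ties <- which(tn == max(tn))
        last <- tab[ties[length(ties)], , drop = FALSE] # last row wins a tie

        if (is.na(last$value_num) || is.na(last$value_unit)) FALSE else {
          isTRUE(compare_quantity(last$value_num, last$value_unit,
                                  crit$comparator, crit$threshold))
        }
      }
    }
  )
  if (crit$negated) !out else out
}

day_start <- function(d) as.POSIXct(as.numeric(as.Date(d)) * 86400,
                                    origin = "1970-01-01", tz = "UTC")

naive_on_day <- function(t, d) {
  ds <- day_start(d)
  t >= ds & t < ds + 86400
}

# does any selected half-open interval overlap day d?
naive_any_interval <- function(tab, start_col, end_col, sel, d, window) {
  if (!any(sel)) return(FALSE)
  s <- tab[[start_col]][sel]
  e <- tab[[end_col]][sel]
  ds <- day_start(d)
  de <- ds + 86400
  # open-ended intervals extend to the end of the window
  e[is.na(e)] <- day_start(window$end_date) + 86400
  any(s < de & e > ds)
}

# enumerate all candidate course starts
naive_dosage <- function(crit, cohort, p, d, keys, tol) {
  spec <- crit$dosage
  tab <- cohort$drug_administrations
  sel <- tab$person_id == p & paste(tab$system, tab$code, sep = "|") %in% keys
  if (!any(sel)) return(FALSE)
  tab <- tab[sel, , drop = FALSE]
  adm_day <- as.integer(floor(as.numeric(tab$administered_at) / 86400))
  dose <- ucum_convert(tab$dose_value, tab$dose_unit, spec$dose$unit$code)
  target <- spec$dose$value * spec$frequency_per_day
  dn <- as.integer(as.Date(d))
  conformant_day <- function(day) {
    i <- adm_day == day
    sum(i) == spec$frequency_per_day &&
      abs(sum(dose[i]) - target) <= tol * target
  }
  dur <- spec$duration_days
  washout <- if (is.finite(dur)) dur else 1
  candidates <- sort(unique(adm_day[adm_day <= dn]))
  for (s in candidates) {
    if (is.finite(dur) && dn > s + dur - 1) next       # course over by d
    if (any(adm_day >= s - washout & adm_day <= s - 1)) next # not a fresh start
    span <- s:dn
    if (all(vapply(span, conformant_day, logical(1)))) return(TRUE)
  }
  FALSE
}
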