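#' Configure a synthetic ICU COVID-19 scenario
#'
#' The generator emulates the setting in which adherence monitoring is
#' typically demonstrated: an ICU cohort during the first two COVID-19
#' pandemic waves, where applicable patients (COVID-19 diagnosis plus an
#' oxygen-supply requirement) should receive a daily 1 mg dexamethasone
#' course for up to 10 days, and where the probability of guideline-
#' conformant treatment steps up at a calendar date — the announcement of
#' trial evidence for dexamethasone efficacy mid-2020.
#'
#' Defaults encode that scenario: a March 2020 – May 2021 window with
#' two-wave admission intensity, a treatment-practice switch on 2020-06-16,
#' low adherence before it and high adherence after it.
#'
#' @param n_patients Number of patients (may be 0).
#' @param window [evaluation_window()] the episodes fall into.
#' @param p_population Probability a patient meets the population criteria
#'   (COVID-19 + oxygen requirement).
#' @param adherence_before,adherence_after Probability that an applicable
#'   patient receives a guideline-conformant course, for episodes starting
#'   before / on-or-after `switch_date`.
#' @param switch_date Calendar date at which treatment practice changes.
#' @param mean_stay_days Mean ICU stay in days (stays are geometric-like).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_patients = 400L,
                            window = evaluation_window("2020-03-01",
                                                       "2021-05-31"),
                            p_population = 0.5,
                            adherence_before = 0.1,
                            adherence_after = 0.75,
                            switch_date = "2020-06-16",
                            mean_stay_days = 7,
                            seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 0 ||
      n_patients != trunc(n_patients)) {
    stop_adhera("n_patients must be a non-negative integer",
                class = "adhera_schema_error")
  }
  stopifnot(inherits(window, "evaluation_window"))
  for (nm in c("p_population", "adherence_before", "adherence_after")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop_adhera(sprintf("%s must be a probability in [0, 1]", nm),
                  class = "adhera_schema_error")
    }
  }
  if (!is.numeric(mean_stay_days) || mean_stay_days <= 0) {
    stop_adhera("mean_stay_days must be positive",
                class = "adhera_schema_error")
  }
  structure(
    list(n_patients = as.integer(n_patients), window = window,
         p_population = p_population,
         adherence_before = adherence_before,
         adherence_after = adherence_after,
         switch_date = as_calendar_date(switch_date, "switch_date"),
         mean_stay_days = mean_stay_days, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Read a scenario configuration from YAML or JSON
#'
#' Field names match the arguments of [scenario_config()]; `window` is given
#' as `{start_date, end_date}`. Missing fields take the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) {
    stop_adhera(sprintf("config file not found: %s", path),
                class = "adhera_io_error")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(cfg)) {
    stop_adhera(sprintf("%s: config must be a mapping/object", path),
                class = "adhera_schema_error", path = "/")
  }
  known <- c("n_patients", "window", "p_population", "adherence_before",
             "adherence_after", "switch_date", "mean_stay_days", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0L) {
    stop_adhera(sprintf("unknown config field(s): %s at /%s",
                        paste(extra, collapse = ", "), extra[1L]),
                class = "adhera_schema_error", path = paste0("/", extra[1L]))
  }
  if (!is.null(cfg$window)) {
    if (is.null(cfg$window$start_date) || is.null(cfg$window$end_date)) {
      stop_adhera("config window needs start_date and end_date at /window",
                  class = "adhera_schema_error", path = "/window")
    }
    cfg$window <- evaluation_window(cfg$window$start_date,
                                    cfg$window$end_date)
  }
  rlang::exec(scenario_config, !!!cfg)
}

# The regimen the synthetic scenario emulates (matches the bundled example
# recommendation): 1 mg dexamethasone once daily for up to 10 days.
.scenario_regimen <- list(
  drug = list(system = "ATC", code = "H02AB02"),
  dose_mg = 1, course_days = 10L,
  covid = list(system = "ICD10", code = "U07.1"),
  oxygen = list(system = "SNOMED", code = "57485005"),
  ward = "ICU"
)

#' Generate a synthetic cohort with known ground truth
#'
#' Draws one ICU episode per patient (admission dates follow a two-wave
#' intensity; stays are geometric-like around `mean_stay_days`). Population
#' members carry a COVID-19 condition over the episode and an oxygen-supply
#' procedure over the acute phase (the first `min(10, stay)` days); half of
#' the non-members carry the condition without the oxygen requirement.
#' Applicable patients receive, with the regime-specific probability, a
#' guideline-conformant dexamethasone course (one 1 mg administration per
#' day from admission, for `min(10, remaining stay)` days); non-conformant
#' applicable patients receive — in equal thirds — no steroid, a triple-dose
#' course, or a course with a missed day (exercising the absent, wrong-dose
#' and gap branches of the dosage semantics).
#'
#' @param config A [scenario_config()].
#' @return A list with elements `cohort` (a [cohort_data()] that passes
#'   [validate_cohort()] with zero findings) and `ground_truth` (a tibble
#'   with one row per patient: episode bounds, `regime`,
#'   `population_member`, `conformant_course`, `mode`, `course_start`).
#' @export
generate_cohort <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  withr::local_seed(config$seed)
  n <- config$n_patients
  reg <- .scenario_regimen
  if (n == 0L) {
    return(list(cohort = cohort_data(),
                ground_truth = empty_ground_truth()))
  }
  wstart <- config$window$start_date
  wend <- config$window$end_date
  ids <- sprintf("P%04d", seq_len(n))

  # two-wave admission intensity (second wave larger)
  wave <- stats::rbinom(n, 1L, 0.6)
  mu <- as.numeric(ifelse(wave == 1L,
                          as.Date("2020-12-01"), as.Date("2020-04-05")))
  sdv <- ifelse(wave == 1L, 35, 20)
  admission <- as.Date(round(stats::rnorm(n, mu, sdv)), origin = "1970-01-01")
  admission <- pmin(pmax(admission, wstart), wend)
  stay <- 1L + stats::rgeom(n, 1 / config$mean_stay_days)

  regime <- ifelse(admission < config$switch_date, "before", "after")
  member <- stats::runif(n) < config$p_population
  p_adh <- ifelse(regime == "before",
                  config$adherence_before, config$adherence_after)
  conformant <- member & (stats::runif(n) < p_adh)
  mode <- rep("conformant", n)
  nonconf <- which(member & !conformant)
  if (length(nonconf) > 0L) {
    mode[nonconf] <- sample(c("absent", "wrong_dose", "gapped"),
                            length(nonconf), replace = TRUE)
  }
  mode[!member] <- "not_applicable"
  acute_days <- pmin(stay, reg$course_days)
  # a 1-day acute phase leaves no day to miss: the gapped failure mode
  # degenerates to receiving no steroid at all
  mode[mode == "gapped" & acute_days == 1L] <- "absent"

  persons <- tibble::tibble(
    person_id = ids,
    birth_year = sample(1930:1995, n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE)
  )

  dt <- function(day, hour) {
    as.POSIXct(as.numeric(day) * 86400 + hour * 3600,
               origin = "1970-01-01", tz = "UTC")
  }
  last_day <- admission + stay - 1L
  encounters <- tibble::tibble(
    person_id = ids, ward_type = reg$ward,
    start = dt(admission, 8), end = dt(last_day, 20)
  )

  covid_flag <- member | (stats::runif(n) < 0.5) # half of non-members too
  ci <- which(covid_flag)
  conditions <- tibble::tibble(
    person_id = ids[ci], system = reg$covid$system, code = reg$covid$code,
    onset = dt(admission[ci], 0),
    abatement = as.POSIXct(rep(NA_real_, length(ci)),
                           origin = "1970-01-01", tz = "UTC")
  )

  pi_ <- which(member)
  procedures <- tibble::tibble(
    person_id = ids[pi_], system = reg$oxygen$system, code = reg$oxygen$code,
    start = dt(admission[pi_], 8),
    end = dt(admission[pi_] + acute_days[pi_] - 1L, 20)
  )

  drug_rows <- purrr::map(seq_len(n), function(i) {
    if (mode[i] %in% c("not_applicable", "absent")) return(NULL)
    len <- acute_days[i]
    offs <- seq_len(len) - 1L
    if (mode[i] == "gapped") {
      offs <- setdiff(offs, 1L) # miss day 2 of the course
      if (length(offs) == 0L) return(NULL)
    }
    dose <- if (mode[i] == "wrong_dose") 3 * reg$dose_mg else reg$dose_mg
    tibble::tibble(
      person_id = ids[i], system = reg$drug$system, code = reg$drug$code,
      dose_value = dose, dose_unit = "mg",
      administered_at = dt(admission[i] + offs, 9)
    )
  })
  drug_administrations <- dplyr::bind_rows(
    c(list(empty_table("drug_administrations")), drug_rows))

  cohort <- cohort_data(
    persons = persons, encounters = encounters, conditions = conditions,
    drug_administrations = drug_administrations,
    observations = empty_table("observations"), procedures = procedures
  )
  ground_truth <- tibble::tibble(
    person_id = ids,
    episode_start = admission, episode_end = last_day,
    regime = regime,
    population_member = member,
    conformant_course = conformant,
    mode = mode,
    course_start = dplyr::if_else(
      mode %in% c("not_applicable", "absent"), as.Date(NA), admission)
  )
  list(cohort = cohort, ground_truth = ground_truth)
}

empty_ground_truth <- function() {
  tibble::tibble(
    person_id = character(0),
    episode_start = as.Date(character(0)), episode_end = as.Date(character(0)),
    regime = character(0), population_member = logical(0),
    conformant_course = logical(0), mode = character(0),
    course_start = as.Date(character(0))
  )
}

#' The worked example recommendation
#'
#' Dexamethasone for critically ill COVID-19 patients requiring oxygen
#' supply: population = ALL_OF(condition COVID-19 ICD-10 U07.1,
#' active oxygen-therapy procedure SNOMED 57485005); intervention = daily
#' administration of 1 mg dexamethasone (ATC H02AB02) for 10 days. This is
#' the recommendation the synthetic scenario generates data for.
#'
#' @param dose_mg Dose per administration in mg (default 1); changing it
#'   creates content-level recommendation variants for update studies.
#' @param version,valid_from Version metadata.
#' @return A [recommendation()].
#' @export
example_recommendation <- function(dose_mg = 1, version = "1.0.0",
                                   valid_from = "2020-06-16") {
  reg <- .scenario_regimen
  recommendation(
    id = "covid19-dexamethasone",
    title = "Dexamethasone in critically ill COVID-19 patients requiring oxygen supply",
    version = version, valid_from = valid_from,
    population = criterion_group("ALL_OF", list(
      criterion("condition",
                concept_code(reg$covid$system, reg$covid$code, "COVID-19")),
      criterion("procedure_active",
                concept_code(reg$oxygen$system, reg$oxygen$code,
                             "Oxygen therapy"))
    )),
    intervention = criterion_group("ALL_OF", list(
      criterion("drug_administration",
                concept_code(reg$drug$system, reg$drug$code, "Dexamethasone"),
                dosage = dosage_spec(quantity(dose_mg, "mg"),
                                     frequency_per_day = 1L,
                                     duration_days = reg$course_days))
    ))
  )
}

# ---- random instances for property-based validation ------------------------

.random_pool <- list(
  conditions = list(c("ICD10", "U07.1"), c("ICD10", "J96.00"),
                    c("ICD10", "I10"), c("SNOMED", "840539006")),
  procedures = list(c("SNOMED", "57485005"), c("SNOMED", "40617009"),
                    c("SNOMED", "265764009")),
  drugs = list(c("ATC", "H02AB02"), c("ATC", "H02AB04"), c("ATC", "J01CA04")),
  observations = list(c("LOINC", "2708-6"), c("LOINC", "3150-0")),
  wards = c("ICU", "IMC", "NORMAL")
)

#' Generate a random valid recommendation
#'
#' Draws a recommendation with random population and intervention criterion
#' trees (nesting depth at most `max_depth`) over a fixed pool of plausible
#' ICU concepts. Uses the current RNG state; seed with [set.seed()] or
#' [withr::with_seed()] for reproducibility. Intended for round-trip and
#' engine-equivalence property tests.
#'
#' @param max_depth Maximum nesting depth of each criterion tree.
#' @return A [recommendation()].
#' @export
random_recommendation <- function(max_depth = 3L) {
  recommendation(
    id = sprintf("rec-%04d", sample.int(9999L, 1L)),
    title = "randomly generated recommendation",
    version = sprintf("%d.%d.%d", sample.int(3L, 1L), sample.int(9L, 1L),
                      sample.int(9L, 1L)),
    valid_from = as.Date("2020-01-01") + sample.int(400L, 1L),
    population = random_tree(max_depth),
    intervention = random_tree(max_depth)
  )
}

random_tree <- function(depth) {
  n <- sample.int(3L, 1L)
  members <- purrr::map(seq_len(n), function(i) {
    if (depth > 1L && stats::runif(1) < 0.35) {
      random_tree(depth - 1L)
    } else {
      random_leaf()
    }
  })
  criterion_group(sample(c("ALL_OF", "ANY_OF"), 1L), members,
                  negated = stats::runif(1) < 0.15)
}

random_leaf <- function() {
  kind <- sample(c("condition", "procedure_active", "drug_administration",
                   "observation", "episode_attribute"), 1L,
                 prob = c(0.3, 0.2, 0.25, 0.15, 0.1))
  pool <- .random_pool
  pick <- function(lst) {
    x <- lst[[sample.int(length(lst), 1L)]]
    concept_code(x[1L], x[2L])
  }
  negated <- stats::runif(1) < 0.15
  switch(kind,
    condition = criterion("condition", pick(pool$conditions),
                          negated = negated),
    procedure_active = criterion("procedure_active", pick(pool$procedures),
                                 negated = negated),
    episode_attribute = criterion(
      "episode_attribute",
      concept_code("SNOMED", sample(pool$wards, 1L)), negated = negated),
    observation = criterion(
      "observation", pick(pool$observations),
      comparator = sample(comparator_ops(), 1L),
      threshold = quantity(sample(80:99, 1L), "%"), negated = negated),
    drug_administration = {
      dosage <- NULL
      if (stats::runif(1) < 0.5) {
        dosage <- dosage_spec(
          quantity(sample(c(1, 2, 4), 1L), "mg"),
          frequency_per_day = sample.int(2L, 1L),
          duration_days = if (stats::runif(1) < 0.2) Inf
                          else sample(2:6, 1L)
        )
      }
      criterion("drug_administration", pick(pool$drugs), dosage = dosage,
                negated = negated)
    }
  )
}

#' Generate a random small evaluation instance
#'
#' A complete, seeded micro-scenario for engine validation: a random
#' recommendation over the shared concept pool plus a random cohort of at
#' most `max_patients` patients over a window of at most `max_days` days,
#' with events (encounters, conditions, procedures, drug administrations at
#' varying doses and units, observations) drawn from the same pool so that
#' criterion truth values are non-trivial.
#'
#' @param seed Integer seed.
#' @param max_patients,max_days Upper bounds on instance size.
#' @return A list with `rec`, `cohort`, `window`.
#' @export
random_instance <- function(seed, max_patients = 20L, max_days = 30L) {
  withr::local_seed(seed)
  n <- sample.int(max_patients, 1L)
  n_days <- sample(5:max_days, 1L)
  wstart <- as.Date("2020-03-01")
  window <- evaluation_window(wstart, wstart + n_days - 1L)
  rec <- random_recommendation()
  pool <- .random_pool
  ids <- sprintf("R%03d", seq_len(n))
  rnd_dt <- function(k) {
    as.POSIXct(as.numeric(wstart) * 86400 +
                 stats::runif(k, 0, n_days * 86400),
               origin = "1970-01-01", tz = "UTC")
  }
  maybe_end <- function(start) {
    len <- stats::runif(length(start), 0.5, 12) * 86400
    out <- start + len
    out[stats::runif(length(start)) < 0.3] <- NA # open-ended
    out
  }
  pick_chr <- function(lst, k) {
    idx <- sample.int(length(lst), k, replace = TRUE)
    list(system = vapply(idx, function(i) lst[[i]][1L], character(1)),
         code = vapply(idx, function(i) lst[[i]][2L], character(1)))
  }
  event_rows <- function(lst, lambda) {
    k_per <- stats::rpois(n, lambda)
    person <- rep(ids, k_per)
    k <- length(person)
    cc <- pick_chr(lst, k)
    list(person = person, system = cc$system, code = cc$code, k = k)
  }

  enc_has <- stats::runif(n) < 0.9
  enc_start <- rnd_dt(n)
  encounters <- tibble::tibble(
    person_id = ids[enc_has],
    ward_type = sample(pool$wards, sum(enc_has), replace = TRUE),
    start = enc_start[enc_has],
    end = maybe_end(enc_start[enc_has])
  )

  ev <- event_rows(pool$conditions, 1.2)
  onset <- rnd_dt(ev$k)
  conditions <- tibble::tibble(
    person_id = ev$person, system = ev$system, code = ev$code,
    onset = onset, abatement = maybe_end(onset)
  )

  ev <- event_rows(pool$procedures, 0.8)
  pstart <- rnd_dt(ev$k)
  procedures <- tibble::tibble(
    person_id = ev$person, system = ev$system, code = ev$code,
    start = pstart, end = maybe_end(pstart)
  )

  # drug administrations: short daily runs at 09:00 (sometimes a second
  # administration at 21:00), varying dose and unit
  drug_rows <- purrr::map(seq_len(n), function(i) {
    n_runs <- stats::rpois(1L, 0.8)
    if (n_runs == 0L) return(NULL)
    purrr::map(seq_len(n_runs), function(r) {
      dcode <- pool$drugs[[sample.int(length(pool$drugs), 1L)]]
      start_off <- sample.int(n_days, 1L) - 1L
      len <- sample.int(7L, 1L)
      offs <- start_off + (seq_len(len) - 1L)
      offs <- offs[offs < n_days]
      if (stats::runif(1) < 0.3 && length(offs) > 1L) {
        offs <- offs[-sample.int(length(offs), 1L)]
      }
      if (length(offs) == 0L) return(NULL)
      second <- stats::runif(1) < 0.3
      hours <- c(9, if (second) 21)
      grid <- expand.grid(off = offs, hour = hours)
      dose_mg <- sample(c(0.5, 1, 1.05, 2, 3, 4), 1L)
      unit <- sample(c("mg", "mg", "mg", "g", "ug"), 1L)
      dose <- switch(unit, mg = dose_mg, g = dose_mg / 1000,
                     ug = dose_mg * 1000)
      tibble::tibble(
        person_id = ids[i], system = dcode[1L], code = dcode[2L],
        dose_value = dose, dose_unit = unit,
        administered_at = as.POSIXct(
          (as.numeric(wstart) + grid$off) * 86400 + grid$hour * 3600,
          origin = "1970-01-01", tz = "UTC")
      )
    })
  })
  drug_administrations <- dplyr::bind_rows(
    c(list(empty_table("drug_administrations")), drug_rows))

  ev <- event_rows(pool$observations, 1.5)
  observations <- tibble::tibble(
    person_id = ev$person, system = ev$system, code = ev$code,
    value_num = round(stats::runif(ev$k, 75, 100), 1),
    value_unit = "%", value_code = NA_character_,
    observed_at = rnd_dt(ev$k)
  )

  persons <- tibble::tibble(
    person_id = ids,
    birth_year = sample(1930:1995, n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE)
  )
  cohort <- cohort_data(
    persons = persons, encounters = encounters, conditions = conditions,
    drug_administrations = drug_administrations,
    observations = observations, procedures = procedures
  )
  list(rec = rec, cohort = cohort, window = window)
}
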