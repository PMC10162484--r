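---
title: "Monitoring guideline recommendation adherence: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring guideline recommendation adherence: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhera)
```

## The problem

Evidence-based clinical practice guidelines state, for a defined patient
population, what should (or should not) be done. Whether a ward actually
follows a recommendation is hard to see from inside routine care: staff must
recognise every situation in which a recommendation applies, and
recommendations change quickly — dramatically so during the COVID-19
pandemic. `adhera` implements the computational core of a clinical decision
support system for this task: it takes a *machine-readable* guideline
recommendation and *tabular* clinical data, and answers, per patient and per
calendar day, two questions:

* **Applicability** — does the recommendation's population definition match
  this patient on this day (and is the patient actually admitted)?
* **Adherence** — given applicability, is the recommended intervention
  being carried out on this day?

Aggregated over a cohort, the two daily counts and their ratio form the
adherence time series a quality officer would monitor.

## The recommendation model

A recommendation document is declarative JSON (schema in
`system.file("schema", "recommendation.schema.json", package = "adhera")`).
Content follows the PICO decomposition used in evidence-based guideline
development: the engine consumes the population (P) and intervention (I)
parts, each a boolean tree (`ALL_OF` / `ANY_OF`, arbitrarily nested,
optionally negated) of terminology-coded criteria:

| criterion kind        | data table             | day-level semantics |
|-----------------------|------------------------|---------------------|
| `condition`           | conditions             | a matching `[onset, abatement)` interval overlaps the day |
| `procedure_active`    | procedures             | as above on `[start, end)` |
| `episode_attribute`   | encounters             | an encounter with the coded ward type covers the day |
| `drug_administration` | drug administrations   | ≥ 1 matching administration that day; with a dosage schedule, the course semantics below |
| `observation`         | observations           | the most recent matching observation at or before the end of the day satisfies the comparator, after unit conversion |

Concepts are coded with ICD-10 (diagnoses), SNOMED CT (procedures,
clinical concepts), ATC (drugs), LOINC (observations) and UCUM (units).
Comparison and outcome elements of PICO may be present in a document but do
not influence evaluation — published adherence semantics are defined on P
and I only, so the reader accepts and ignores them rather than guessing a
meaning.

Versioning is content-only: versions of a recommendation share an `id` and
differ in `valid_from`; `select_version()` picks the version with the latest
`valid_from` on or before a date (inclusive: a version released on a day
applies that day). Swapping documents changes the engine's behaviour with no
code change — the property that makes *living guidelines* maintainable.

## Clinical data model and conventions

Patient data arrive as six CSV tables (persons, encounters, conditions,
drug administrations, observations, procedures) in a minimal common data
model; any EHR export (OMOP, FHIR, a proprietary system) can be converted to
it by a thin ETL step. Loading is strict: malformed rows, unparseable
timestamps and references to unknown patients are errors, not silent
repairs; `validate_cohort()` additionally reports machine-readable findings.

Conventions that define the day-level semantics:

* **Granularity is the calendar day.** Recommendation language ("daily
  administration…") and cohort monitoring are day-based; finer granularity
  would add complexity without changing any verdict the model can express.
* **Intervals are half-open** `[start, end)`. An event ending at 00:00 of
  day *d* does not cover *d*. Date-only timestamps mean 00:00.
* **Open-ended intervals** (no end recorded) extend to the end of the
  evaluation window.
* **Closed world.** Absence of a record makes a criterion false (before
  negation). The alternative — three-valued logic — is not defined by
  published adherence-monitoring semantics; conservative falsity plus the
  per-criterion audit trail (`leaf_results`) was chosen instead, so a
  reviewer can always see *which* leaf failed and check the raw data.
* **Applicability is gated on admission.** Only patients with an active
  encounter on a day can be applicable; this makes ward-level counts
  meaningful.

## Dosage course semantics

The worked intervention throughout the package is *daily administration of
1 mg dexamethasone for 10 days*. A `dosage_spec` (dose per administration,
administrations per day, course length in days, possibly unbounded) is
evaluated with course semantics: a day *d* is fulfilled iff there is a
course start *s* with

* *s* ≤ *d* ≤ *s* + duration − 1,
* every day in [*s*, *d*] *conformant*: exactly `frequency_per_day`
  matching administrations whose total dose is within a relative tolerance
  (default 0.10, configurable — clinical rounding makes exact floating-point
  equality wrong) of the prescribed daily total, after UCUM conversion, and
* *s* is a *fresh* start: no matching administration in the preceding
  `duration_days` (for unbounded regimens: on the previous day).

Consequences, all deliberate:

* A patient mid-course counts as fulfilled ("ongoing-adherent") — no
  lookahead is required, so a verdict for today never depends on future
  data. Whether adherence "today" should require the course to eventually
  complete is genuinely open; the no-lookahead choice is the only one
  compatible with real-time monitoring.
* Days after a completed course are not fulfilled.
* A missed day breaks the course, and the resumed run is *not* a fresh
  course while earlier administrations fall inside the washout window —
  course attribution goes to the earliest possible start. Without this
  rule any single conformant day would count as a fresh one-day course and
  a gapped course would be indistinguishable from a correct one.
* Over-administration (more than the scheduled count on a day) breaks
  conformance — the schedule asks for an exact daily pattern.

UCUM support is a fixed mass/time/percent subset (`mg`, `g`, `ug`, `%`,
`h`, `d`) with a static conversion table; full UCUM grammar parsing is out
of scope, and incomparable units are a loud error naming both units.

## Execution model and its validation

`compile_plan()` resolves every leaf concept through a `codemap` (strict by
default: an unmapped concept is a compile error naming the criterion's JSON
path, because a silently unmapped code would yield a false "not applicable"
verdict that clinicians could not detect). The compiled plan is pure data;
evaluation runs each leaf once over the person × day grid as a vectorised
logical mask and combines masks up the tree.

The package carries a second, deliberately naive evaluator
(`evaluate_cohort_naive()`) that loops over every (patient, day, leaf)
triple straight from the declarative recommendation with no compilation and
no shared execution code. The test suite requires exact agreement between
the two on hundreds of randomly generated instances (random criterion
trees of depth ≤ 3 over a fixed concept pool, random event data, ≤ 20
patients × ≤ 30 days) — the engine-level guarantee the rest of the
validation rests on. Dosage semantics are additionally checked scenario by
scenario (complete, mid-course, gapped, wrong-dose, over-long, tolerance
boundary) against the enumerated-course-start brute force on every day of a
30-day window.

## The synthetic validation scenario

Real hospital data cannot ship with a package, so `generate_cohort()`
creates a seeded ICU COVID-19 cohort with known ground truth. Defaults are
the package's validation study conditions and deliberately not a dial to
turn:

* window March 2020 – May 2021, admissions drawn from a two-bump (two-wave)
  intensity, the second wave larger;
* one ICU episode per patient; stays geometric-like with mean
  `mean_stay_days = 7` (a realistic ICU COVID-19 stay scale);
* `p_population = 0.5` of patients meet the population definition: a
  COVID-19 condition over the episode plus an oxygen-supply procedure over
  the acute phase, `min(10, stay)` days (oxygen requirement typically
  resolves; this also makes the applicable period coincide with the
  maximal course window). Half of the non-members carry the diagnosis
  without the oxygen requirement, so partially-matching patients exist;
* an applicable patient receives a guideline-conformant course (1 mg
  dexamethasone daily from admission for `min(10, remaining stay)` days)
  with probability `adherence_before = 0.1` if admitted before
  `switch_date = 2020-06-16` (the first public announcement of trial
  evidence for dexamethasone) and `adherence_after = 0.75` after it —
  the step-change scenario;
* non-conformant applicable patients split equally into *no steroid*,
  *wrong dose* (×3) and *gapped course* (the second course day is missed),
  exercising each failure branch of the dosage semantics. A 1-day acute
  phase leaves no day to miss, so its "gapped" mode degenerates to *no
  steroid*.

Because a conformant course spans exactly the applicable days, the
patient-level estimator — the fraction of applicable patients adherent on
*every* applicable day, computed by `adherence_by_regime()` — is exactly a
binomial proportion of the configured rate, and the validation suite checks
that it falls inside the exact binomial 95% envelope in both regimes for at
least 19 of 20 fixed seeds, with a positive post-switch step in all of
them. The *daily* fraction is a different quantity: gapped patients are
adherent on their first course day (a one-day course started that day is
ongoing-adherent) and patients outnumbering their courses dilute it, so it
sits slightly above the configured rate; it is checked against the envelope
only in the constant-rate scenario where that bias is small relative to the
band.

What the generator does **not** emulate — and what passing tests therefore
do not show: transfer patients treated before arrival (the classic cause of
a sub-100% measured ceiling in real data), comorbidity structure,
pharmacokinetics, multi-episode patients, coding errors and missingness in
real EHR extracts. Engine correctness transfers to real data; measured
adherence levels do not.

## Numerical and design notes

* Evaluation is fully deterministic; the only randomness in the package is
  in the generators, always behind an explicit seed.
* `run_evaluation()` writes no wall-clock timestamp into `report.json`, so
  identical inputs give byte-identical outputs (fractions serialized with
  six decimals; undefined fractions as empty/null).
* The daily fraction is undefined (`NA`/null), not zero, on days with no
  applicable patient.
* Ties among observations with identical timestamps resolve to the last
  row in file order, in both evaluators.
* Degenerate inputs: an empty cohort yields an all-zero series with
  undefined fractions; a window of one day is valid; `n_patients = 0` is a
  valid scenario.
* Problem sizes in the validation suite (200 random oracle instances,
  20 recovery seeds at 400 patients × 457 days, 500+ monotonicity cases)
  were chosen so the whole suite completes in a couple of minutes on one
  CPU while keeping the binomial envelopes tight enough to detect the
  failure modes the generator plants.

## Limitations

* Single recommendations only: multi-step clinical pathways with decision
  points are out of scope.
* Flat code lists in the terminology map — no subsumption or hierarchy
  expansion; an ECL-capable terminology server would slot in behind
  `resolve_codes()`.
* The UCUM subset covers the units the shipped criteria need; extending it
  is a table edit, not a design change.
* No uncertainty-aware or preference-sensitive recommendations; a
  recommendation is a boolean verdict machine.
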