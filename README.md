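# adhera

Automated monitoring of adherence to clinical guideline recommendations.

Hospital staff are expected to recognise every situation in which an
evidence-based guideline recommendation applies — across many patients, many
simultaneously applicable recommendations, and recommendations that change
as evidence accrues. `adhera` implements the computational core of a
clinical decision support system for this problem: it compiles declarative,
machine-readable guideline recommendations into executable
event-condition-action rules and evaluates them, per patient and per
calendar day, against clinical data in a small tabular common data model.
It is aimed at health-informatics engineers and quality-management teams
who want ward- or hospital-level adherence monitoring without hard-coding
any recommendation into software.

## The model

A recommendation follows the PICO decomposition of evidence-based medicine;
the engine consumes its **P** (population) and **I** (intervention) parts,
each a boolean tree (`ALL_OF`/`ANY_OF`, nestable, negatable) of
terminology-coded criteria (ICD-10, SNOMED CT, ATC, LOINC, UCUM). For
patient *p* and day *d* the engine computes

* `population_applicable(p, d)` — an active encounter covers *d* **and**
  the population tree is true, with closed-world semantics (no record ⇒
  false) and half-open `[start, end)` event intervals;
* `intervention_fulfilled(p, d)` — the intervention tree is true; a dosage
  schedule (dose × frequency × duration) is fulfilled on *d* iff *d* lies
  inside a fresh-start course whose every day so far carries the scheduled
  administrations within a relative dose tolerance (default 10%);
* `adherent(p, d) = population_applicable(p, d) ∧ intervention_fulfilled(p, d)`.

Per day, the cohort series counts `n_applicable`, `n_adherent` and their
fraction — the two panels of a classic adherence-monitoring dashboard.
Recommendation content is data, not code: new versions (`select_version()`
picks the one valid on a date) change results with zero engine changes.

## Worked example

The package bundles the dexamethasone recommendation (1 mg daily for 10
days for critically ill COVID-19 patients requiring oxygen supply) and a
five-patient fixture cohort:

```r
library(adhera)

rec <- parse_recommendation(
  system.file("extdata", "recommendation-dexamethasone.json", package = "adhera"))
cohort <- load_cohort(
  system.file("extdata", "fixture-cohort", package = "adhera"))
plan <- compile_plan(rec, load_codemap(
  system.file("extdata", "codemap-identity.csv", package = "adhera")))

ev <- evaluate_cohort(plan, cohort, evaluation_window("2020-06-01", "2020-06-30"))
ev
#> <cohort_evaluation> covid19-dexamethasone (version 1.0.0), 2020-06-01 .. 2020-06-30
#>   30 patient-days applicable, 11 adherent (36.7%)

tidy(ev)   # the day-by-day series
#> # A tibble: 30 × 4
#>   date       n_applicable n_adherent fraction
#>   <date>            <int>      <int>    <dbl>
#> 1 2020-06-01            1          1    1
#> 2 2020-06-02            1          1    1
#> 3 2020-06-03            2          2    1
#> 4 2020-06-04            2          1    0.5
#> 5 2020-06-05            3          1    0.333
#> # …

summarize_patient_adherence(ev)
#> # A tibble: 5 × 5
#>   person_id n_applicable_days n_adherent_days any_adherent fully_adherent
#> 1 F01                      10              10 TRUE         TRUE
#> 2 F02                      10               0 FALSE        FALSE
#> 3 F03                      10               1 TRUE         FALSE
#> 4 F04                       0               0 FALSE        FALSE
#> 5 F05                       0               0 FALSE        FALSE
```

Reading the patient table: F01 received the full course (adherent on all 10
applicable days); F02 received triple the recommended dose (never
adherent); F03 missed the second course day — adherent only on the first
day, because a course that spans a gap is broken and a restart inside the
washout window is not a fresh course; F04 lacks the COVID-19 diagnosis
(never applicable); F05 was never admitted, so the encounter gate keeps
every day non-applicable. `autoplot(ev)` draws the two-panel
counts/fraction figure.

A seeded synthetic ICU COVID-19 scenario with known ground truth — two
admission waves, an adherence step-up at the June 2020 dexamethasone
evidence announcement, and planted non-adherence modes (no steroid, wrong
dose, gapped course) — comes from `generate_cohort(scenario_config())`;
`adherence_by_regime()` then recovers the configured pre-/post-switch
adherence rates from the evaluator's output alone.

A thin command line sits on top (`system.file("cli", "adhera", package =
"adhera")`) with subcommands `evaluate`, `synthesize` and `validate`.

## Package layout

* `R/recommendation.R`, `inst/schema/` — recommendation dialect: parse,
  serialize, validate, version selection
* `R/clinical-data.R` — the six-table common data model, CSV I/O, findings
* `R/terminology.R` — guideline-to-local code mapping
* `R/evaluate.R`, `R/naive.R` — compiled rule engine and the independent
  brute-force reference evaluator
* `R/synthetic.R` — scenario generator with ground truth; random instance
  generators for property testing
* `R/reporting.R`, `inst/cli/` — end-to-end runs, file outputs, CLI
* `vignettes/adherence-engine.Rmd` — model, semantics, design decisions,
  limitations
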