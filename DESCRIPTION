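Package: adhera
Title: Guideline Recommendation Adherence Monitoring from Tabular Clinical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles declarative, PICO-structured clinical guideline
    recommendations (population and intervention criterion trees coded with
    ICD-10, SNOMED CT, ATC, LOINC and UCUM) into executable
    event-condition-action rules and evaluates, per patient and per calendar
    day, whether each recommendation is applicable and adhered to, against
    clinical data supplied as CSV tables in a small common data model.
    Includes terminology code mapping, cohort-level time-series aggregation
    with ggplot2 visualisation, and a seeded synthetic ICU COVID-19 cohort
    generator with known ground truth for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
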