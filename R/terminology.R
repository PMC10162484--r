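#' Create a concept code map
#'
#' Guideline criteria are coded in standard terminologies, but local patient
#' data may use different (or additional) codes for the same concept. A code
#' map translates each guideline concept to the list of local codes that
#' count as a match; one-to-many entries are interpreted as OR (any local
#' code matching satisfies the concept).
#'
#' In strict mode (the default) a concept without an entry is an error at
#' compile time — silently unmatched codes would yield false "not
#' applicable" verdicts, which clinicians could not trust. With
#' `strict = FALSE` an unmapped concept falls back to the identity mapping
#' (the concept matches itself) with a warning.
#'
#' @param entries Tibble (or data frame) with columns `guideline_system`,
#'   `guideline_code`, `local_system`, `local_code`. May have zero rows.
#' @param strict Logical; error on unmapped concepts (default `TRUE`).
#' @return An object of class `codemap`.
#' @seealso [load_codemap()], [resolve_codes()]
#' @export
codemap <- function(entries = NULL, strict = TRUE) {
  cols <- c("guideline_system", "guideline_code", "local_system", "local_code")
  if (is.null(entries)) {
    entries <- tibble::as_tibble(stats::setNames(
      rep(list(character(0)), 4L), cols))
  }
  entries <- tibble::as_tibble(entries)
  missing <- setdiff(cols, names(entries))
  if (length(missing) > 0L) {
    stop_adhera(sprintf("codemap is missing column(s): %s",
                        paste(missing, collapse = ", ")),
                class = "adhera_terminology_error")
  }
  entries <- entries[cols]
  for (sc in c("guideline_system", "local_system")) {
    bad <- setdiff(unique(entries[[sc]]), concept_systems())
    if (length(bad) > 0L) {
      stop_adhera(sprintf("codemap column %s contains unknown system(s): %s",
                          sc, paste(bad, collapse = ", ")),
                  class = "adhera_terminology_error")
    }
  }
  if (anyDuplicated(entries)) {
    warning("dropping duplicate codemap rows", call. = FALSE)
    entries <- dplyr::distinct(entries)
  }
  structure(list(entries = entries, strict = isTRUE(strict)),
            class = "codemap")
}

#' @export
print.codemap <- function(x, ...) {
  n_concepts <- nrow(dplyr::distinct(
    x$entries, .data$guideline_system, .data$guideline_code))
  cat(sprintf("<codemap> %d guideline concept(s), %d local code(s), %s mode\n",
              n_concepts, nrow(x$entries),
              if (x$strict) "strict" else "lenient"))
  invisible(x)
}

#' Load a concept code map from CSV
#'
#' Reads a UTF-8 CSV with header
#' `guideline_system,guideline_code,local_system,local_code`. Multiple rows
#' for the same guideline concept aggregate into one entry with several
#' local codes; exact duplicate rows are dropped with a warning.
#'
#' @param csv_path Path to the mapping CSV.
#' @inheritParams codemap
#' @return A [codemap()].
#' @export
load_codemap <- function(csv_path, strict = TRUE) {
  if (!file.exists(csv_path)) {
    stop_adhera(sprintf("codemap file not found: %s", csv_path),
                class = "adhera_io_error")
  }
  tab <- readr::read_csv(
    csv_path,
    col_types = readr::cols(
      guideline_system = readr::col_character(),
      guideline_code = readr::col_character(),
      local_system = readr::col_character(),
      local_code = readr::col_character(),
      .default = readr::col_skip()
    ),
    na = character(0), progress = FALSE
  )
  missing <- setdiff(
    c("guideline_system", "guideline_code", "local_system", "local_code"),
    names(tab))
  if (length(missing) > 0L) {
    stop_adhera(sprintf("%s: missing column(s) %s",
                        csv_path, paste(missing, collapse = ", ")),
                class = "adhera_io_error")
  }
  incomplete <- which(!stats::complete.cases(tab) |
                        rowSums(tab == "") > 0)
  if (length(incomplete) > 0L) {
    stop_adhera(sprintf("%s: malformed row at line %d",
                        csv_path, incomplete[1L] + 1L),
                class = "adhera_io_error")
  }
  codemap(tab, strict = strict)
}

#' Resolve a guideline concept to local codes
#'
#' Returns the local concept codes that count as a match for a guideline
#' concept. With an entry present, its local codes; absent and
#' `strict = FALSE`, the identity mapping (the concept itself, with a
#' warning); absent and `strict = TRUE`, an error naming the concept.
#' Never returns an empty list.
#'
#' @param map A [codemap()].
#' @param concept A [concept_code()].
#' @return A list of [concept_code()] objects.
#' @export
#' @examples
#' cm <- codemap(tibble::tibble(
#'   guideline_system = "ATC", guideline_code = "H02AB02",
#'   local_system = "ATC", local_code = c("H02AB02", "H02AB-LOCAL")))
#' resolve_codes(cm, concept_code("ATC", "H02AB02"))
resolve_codes <- function(map, concept) {
  stopifnot(inherits(map, "codemap"), inherits(concept, "concept_code"))
  sel <- map$entries$guideline_system == concept$system &
    map$entries$guideline_code == concept$code
  if (any(sel)) {
    return(purrr::map2(map$entries$local_system[sel],
                       map$entries$local_code[sel], concept_code))
  }
  if (map$strict) {
    stop_adhera(sprintf("no mapping for concept %s|%s in strict mode",
                        concept$system, concept$code),
                class = "adhera_terminology_error",
                concept = concept)
  }
  if (!isTRUE(map$identity)) {
    warning(sprintf("concept %s|%s unmapped; using identity mapping",
                    concept$system, concept$code), call. = FALSE)
  }
  list(concept)
}

#' Identity code map
#'
#' Convenience constructor for the common case where guideline and local
#' data share the same codes: an empty, non-strict map under which every
#' concept resolves to itself.
#'
#' @return A [codemap()] with `strict = FALSE` and no entries.
#' @export
identity_codemap <- function() {
  cm <- codemap(strict = FALSE)
  cm$identity <- TRUE
  cm
}
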