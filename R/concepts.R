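#' Terminology systems understood by the engine
#'
#' The closed set of terminology identifiers a [concept_code()] may carry:
#' ICD-10 for diagnoses, SNOMED CT for clinical concepts and procedures,
#' ATC for drugs, LOINC for observations and laboratory values, and UCUM
#' for units of measure.
#'
#' @return Character vector of valid `system` values.
#' @export
#' @examples
#' concept_systems()
concept_systems <- function() {
  c("ICD10", "SNOMED", "ATC", "LOINC", "UCUM")
}

#' Create a terminology-coded concept
#'
#' A concept code is a pair of a terminology `system` and a `code` within it,
#' optionally with a human-readable `display` label. All clinical content in
#' a recommendation (conditions, drugs, observations, procedures, units) is
#' expressed through concept codes so that the evaluation engine never needs
#' to understand free text.
#'
#' @param system Terminology identifier; one of [concept_systems()].
#' @param code Non-empty code string within the terminology.
#' @param display Optional human-readable label.
#' @return An object of class `concept_code`.
#' @export
#' @examples
#' concept_code("ICD10", "U07.1", "COVID-19")
#' concept_code("ATC", "H02AB02", "Dexamethasone")
concept_code <- function(system, code, display = NULL) {
  if (!is.character(system) || length(system) != 1L ||
      !(system %in% concept_systems())) {
    stop_adhera(
      sprintf(
        "unknown terminology system %s (expected one of %s)",
        deparse1(system), paste(concept_systems(), collapse = ", ")
      ),
      class = "adhera_terminology_error"
    )
  }
  if (!is.character(code) || length(code) != 1L || is.na(code) || !nzchar(code)) {
    stop_adhera("concept code must be a non-empty string",
                class = "adhera_schema_error")
  }
  structure(
    list(system = system, code = code,
         display = if (!is.null(display)) as.character(display)[[1L]]),
    class = "concept_code"
  )
}

#' @export
format.concept_code <- function(x, ...) {
  lab <- if (!is.null(x$display)) paste0(" (", x$display, ")") else ""
  paste0("<", x$system, "|", x$code, ">", lab)
}

#' @export
print.concept_code <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

concept_key <- function(concept) paste(concept$system, concept$code, sep = "|")

#' Create a quantity with a UCUM unit
#'
#' @param value Finite numeric value.
#' @param unit UCUM unit code as a string (e.g. `"mg"`, `"%"`) or a
#'   [concept_code()] with system `"UCUM"`.
#' @return An object of class `quantity` with fields `value` and `unit`.
#' @export
#' @examples
#' quantity(1, "mg")
#' quantity(94, "%")
quantity <- function(value, unit) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop_adhera("quantity value must be a single finite number",
                class = "adhera_schema_error")
  }
  if (is.character(unit)) unit <- concept_code("UCUM", unit)
  if (!inherits(unit, "concept_code") || unit$system != "UCUM") {
    stop_adhera("quantity unit must be a UCUM concept code",
                class = "adhera_schema_error")
  }
  ucum_dimension(unit$code) # validates membership in the supported subset
  structure(list(value = as.numeric(value), unit = unit), class = "quantity")
}

#' @export
format.quantity <- function(x, ...) paste0(x$value, " ", x$unit$code)

#' @export
print.quantity <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Supported UCUM subset: factors convert a value to its dimension's base unit
# (mass -> mg, time -> h, percent -> %). Full UCUM parsing is out of scope.
.ucum_table <- data.frame(
  code = c("mg", "g", "ug", "%", "h", "d"),
  dimension = c("mass", "mass", "mass", "percent", "time", "time"),
  factor = c(1, 1000, 0.001, 1, 1, 24),
  stringsAsFactors = FALSE
)

#' Supported UCUM units
#'
#' The engine supports a fixed mass/time/percent subset of UCUM: `mg`, `g`,
#' `ug` (microgram), `%`, `h`, `d`.
#'
#' @return A tibble with columns `code`, `dimension`, `factor` (conversion to
#'   the dimension's base unit: mg, h, or %).
#' @export
ucum_units <- function() tibble::as_tibble(.ucum_table)

ucum_dimension <- function(code) {
  i <- match(code, .ucum_table$code)
  if (is.na(i)) {
    stop_adhera(sprintf("unsupported UCUM unit '%s' (supported: %s)",
                        code, paste(.ucum_table$code, collapse = ", ")),
                class = "adhera_unit_error")
  }
  .ucum_table$dimension[[i]]
}

#' Convert a value between comparable UCUM units
#'
#' Values convert within a dimension (e.g. mg/g/ug); converting across
#' dimensions (e.g. mg to %) is an error naming both units.
#'
#' @param value Numeric vector.
#' @param from,to UCUM unit codes (recycled against `value`).
#' @return Numeric vector in unit `to`.
#' @export
#' @examples
#' ucum_convert(1, "g", "mg") # 1000
ucum_convert <- function(value, from, to) {
  i_from <- match(from, .ucum_table$code)
  i_to <- match(to, .ucum_table$code)
  bad <- c(from[is.na(i_from)], to[is.na(i_to)])
  if (length(bad) > 0L) {
    stop_adhera(sprintf("unsupported UCUM unit '%s' (supported: %s)",
                        bad[[1L]], paste(.ucum_table$code, collapse = ", ")),
                class = "adhera_unit_error")
  }
  df <- .ucum_table$dimension[i_from]
  dt <- .ucum_table$dimension[i_to]
  mismatch <- which(df != dt)
  if (length(mismatch) > 0L) {
    k <- mismatch[[1L]]
    stop_adhera(sprintf(
      "incomparable units: '%s' (%s) vs '%s' (%s)",
      rep_len(from, length(df))[k], df[k],
      rep_len(to, length(dt))[k], dt[k]),
      class = "adhera_unit_error")
  }
  value * .ucum_table$factor[i_from] / .ucum_table$factor[i_to]
}

# Apply an observation comparator after unit normalisation.
compare_quantity <- function(value, unit, op, threshold) {
  v <- ucum_convert(value, unit, threshold$unit$code)
  t <- threshold$value
  switch(op,
    "<"  = v < t,
    "<=" = v <= t,
    "="  = v == t,
    ">=" = v >= t,
    ">"  = v > t,
    stop_adhera(sprintf("unknown comparator operator '%s'", op),
                class = "adhera_schema_error")
  )
}

comparator_ops <- function() c("<", "<=", "=", ">=", ">")

# Shared condition constructor so callers can test error classes.
stop_adhera <- function(message, class = "adhera_error", ...) {
  rlang::abort(message, class = c(class, "adhera_error"), ...)
}
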