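#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cohort evaluation into its day series
#'
#' @param x A `cohort_evaluation` from [evaluate_cohort()].
#' @param ... Unused.
#' @return The series tibble: `date`, `n_applicable`, `n_adherent`,
#'   `fraction`.
#' @method tidy cohort_evaluation
#' @export
tidy.cohort_evaluation <- function(x, ...) {
  x$series
}

#' One-row summary of a cohort evaluation
#'
#' @param x A `cohort_evaluation` from [evaluate_cohort()].
#' @param ... Unused.
#' @return A one-row tibble: recommendation id/version, cohort and window
#'   size, applicable and adherent patient-day totals, the number of
#'   patients ever applicable, and the mean of the defined daily adherent
#'   fractions.
#' @method glance cohort_evaluation
#' @export
glance.cohort_evaluation <- function(x, ...) {
  per_patient <- summarize_patient_adherence(x$day_results)
  fr <- x$series$fraction
  tibble::tibble(
    recommendation_id = x$plan$id,
    recommendation_version = x$plan$version,
    n_patients = length(unique(x$day_results$person_id)),
    n_days = nrow(x$series),
    patient_days_applicable = sum(x$series$n_applicable),
    patient_days_adherent = sum(x$series$n_adherent),
    n_patients_applicable = sum(per_patient$n_applicable_days > 0L),
    n_patients_fully_adherent = sum(per_patient$fully_adherent),
    mean_daily_fraction = if (any(!is.na(fr))) mean(fr, na.rm = TRUE)
                          else NA_real_
  )
}

#' Plot a cohort evaluation as the classic two-panel adherence figure
#'
#' Top panel: number of patients to which the recommendation is applicable
#' and number treated according to it, per day. Bottom panel: the adherent
#' fraction of applicable patients. A vertical line can mark a guideline
#' switch date.
#'
#' @param object A `cohort_evaluation`.
#' @param switch_date Optional `Date`/string to mark with a vertical line.
#' @param ... Unused.
#' @return A patchwork object stacking the two ggplots.
#' @method autoplot cohort_evaluation
#' @export
autoplot.cohort_evaluation <- function(object, switch_date = NULL, ...) {
  plot_adherence_series(object$series, switch_date = switch_date)
}

#' @rdname autoplot.cohort_evaluation
#' @param series A series tibble (`date`, `n_applicable`, `n_adherent`,
#'   `fraction`).
#' @export
plot_adherence_series <- function(series, switch_date = NULL) {
  if (!requireNamespace("patchwork", quietly = TRUE)) {
    stop_adhera("plotting requires the 'patchwork' package",
                class = "adhera_io_error")
  }
  long <- series |>
    tidyr::pivot_longer(c("n_applicable", "n_adherent"),
                        names_to = "measure", values_to = "n_patients") |>
    dplyr::mutate(measure = dplyr::recode(.data$measure,
                                          n_applicable = "applicable",
                                          n_adherent = "adherent"))
  vline <- if (!is.null(switch_date)) {
    ggplot2::geom_vline(xintercept = as_calendar_date(switch_date, "switch_date"),
                        linetype = "dashed", colour = "grey40")
  }
  p1 <- ggplot2::ggplot(long, ggplot2::aes(x = .data$date,
                                           y = .data$n_patients,
                                           colour = .data$measure)) +
    ggplot2::geom_line() +
    vline +
    ggplot2::scale_colour_manual(values = c(applicable = "#7b3294",
                                            adherent = "#e66101")) +
    ggplot2::labs(x = NULL, y = "patients", colour = NULL) +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(series, ggplot2::aes(x = .data$date,
                                             y = .data$fraction)) +
    ggplot2::geom_line(na.rm = TRUE, colour = "#e66101") +
    vline +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "date", y = "adherent fraction") +
    ggplot2::theme_minimal()
  patchwork::wrap_plots(p1, p2, ncol = 1L)
}
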