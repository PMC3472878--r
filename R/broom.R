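#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the alert log of a monitoring run
#'
#' @param x A `carewatch_run` from [run_stream()]/[monitor_stream()].
#' @param ... Unused.
#' @return The alert tibble: `t`, `patient_id`, `situation`, `phase`,
#'   `detail` (list-column of triggering values).
#' @export
tidy.carewatch_run <- function(x, ...) x$alerts

#' One-row summary of a monitoring run
#'
#' @param x A `carewatch_run`.
#' @param ... Unused.
#' @return A one-row tibble: number of patients and events processed,
#'   alerts raised/cleared, and the physiological and treatment raise
#'   totals.
#' @export
glance.carewatch_run <- function(x, ...) {
  tibble(
    n_patients = length(x$patients),
    n_events = x$n_events,
    n_raised = sum(x$alerts$phase == "RAISED"),
    n_cleared = sum(x$alerts$phase == "CLEARED"),
    physiological_raised = attr(x$counts, "physiological_total"),
    treatment_raised = attr(x$counts, "treatment_total")
  )
}
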