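#' Plot the alert timeline of a monitoring run
#'
#' Raised/cleared intervals per situation (segments) with the individual
#' alert events overlaid, facetted by patient.
#'
#' @param object A `carewatch_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.carewatch_run <- function(object, ...) {
  alerts <- object$alerts
  iv <- alert_intervals(alerts)
  p <- ggplot2::ggplot()
  if (nrow(iv)) {
    p <- p + ggplot2::geom_segment(
      data = iv,
      ggplot2::aes(x = .data$raised_at, xend = .data$cleared_at,
                   y = .data$situation, yend = .data$situation),
      linewidth = 3, colour = "firebrick", alpha = 0.6)
  }
  if (nrow(alerts)) {
    p <- p + ggplot2::geom_point(
      data = alerts,
      ggplot2::aes(x = .data$t, y = .data$situation, shape = .data$phase))
  }
  p +
    ggplot2::facet_wrap(~patient_id, ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL, shape = NULL,
                  title = "Alarm and alert timeline") +
    ggplot2::theme_minimal()
}

#' Raise/clear intervals from an alert log
#'
#' Pairs each `RAISED` event with its matching `CLEARED` event per
#' (patient, situation); an interval still open at the end of the log gets
#' `NA` as its clear time.
#'
#' @param alerts An alert tibble or `carewatch_run`.
#' @return A tibble with `patient_id`, `situation`, `raised_at`,
#'   `cleared_at`.
#' @export
alert_intervals <- function(alerts) {
  if (inherits(alerts, "carewatch_run")) alerts <- alerts$alerts
  alerts <- alerts[alerts$phase %in% c("RAISED", "CLEARED"), , drop = FALSE]
  if (!nrow(alerts)) {
    return(tibble(patient_id = character(), situation = character(),
                  raised_at = cw_posix(numeric()),
                  cleared_at = cw_posix(numeric())))
  }
  out <- alerts |>
    group_by(.data$patient_id, .data$situation) |>
    dplyr::group_modify(function(g, key) {
      g <- g[order(cw_time(g$t)), ]
      up <- which(g$phase == "RAISED")
      down <- which(g$phase == "CLEARED")
      tibble(raised_at = g$t[up],
             cleared_at = cw_posix(vapply(up, function(i) {
               j <- down[down > i]
               if (length(j)) cw_time(g$t[j[1]]) else NA_real_
             }, numeric(1))))
    }) |>
    ungroup()
  out[order(cw_time(out$raised_at), out$patient_id), ]
}

#' Plot a vital-sign stream against its alarm criteria
#'
#' Line plot of the reported vitals, facetted per vital with free scales,
#' with the alarm criteria drawn as dashed horizontal lines.
#'
#' @param samples A tibble of [physiological_sample()] rows.
#' @param cfg A [threshold_config()] supplying the criterion lines.
#' @param vitals Which vital columns to show.
#' @return A ggplot object.
#' @export
plot_vitals <- function(samples, cfg = default_thresholds(),
                        vitals = c("heart_rate", "body_temp",
                                   "blood_pressure", "spo2", "breath_rate")) {
  long <- tidyr::pivot_longer(as_tibble(samples)[, c("patient_id", "t", vitals)],
                              dplyr::all_of(vitals),
                              names_to = "vital", values_to = "value")
  lims <- tibble(
    vital = rep(c("heart_rate", "blood_pressure", "breath_rate", "spo2",
                  "body_temp"), times = c(2, 2, 2, 1, 2)),
    criterion = c(cfg$hr_lo, cfg$hr_hi, cfg$bp_lo, cfg$bp_hi,
                  cfg$breath_lo, cfg$breath_hi, cfg$spo2_lo,
                  cfg$temp_lo, cfg$temp_hi))
  lims <- lims[lims$vital %in% vitals, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_hline(data = lims,
                        ggplot2::aes(yintercept = .data$criterion),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_grid(vital ~ patient_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
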