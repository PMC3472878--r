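#' Construct a physiological sample
#'
#' One timestamped multi-sensor measurement.  Samples are plain tibble rows
#' so that streams of them are ordinary data frames; every sensor field is
#' optional (`NA` means "not reported in this sample") because real devices
#' report asynchronously.  The rule engine only evaluates present values.
#'
#' @param patient_id Patient identifier (character).
#' @param t Timestamp: `POSIXct`, ISO-8601 string, or numeric seconds.
#' @param heart_rate Heart rate, beats/min.
#' @param body_temp Body temperature, degrees Celsius.
#' @param blood_pressure Systolic blood pressure, mmHg.
#' @param spo2 Blood oxygen saturation, percent (0--100).
#' @param breath_rate Breath rate, breaths/min.
#' @param ecg_amp ECG peak amplitude, mV.
#' @param ecg_rr_cv Coefficient of variation of the ECG RR interval.
#' @return A one-row tibble with the standard sample columns.
#' @examples
#' physiological_sample("p1", "2026-01-01T08:00:00", heart_rate = 72, spo2 = 97)
#' @export
physiological_sample <- function(patient_id, t,
                                 heart_rate = NA_real_, body_temp = NA_real_,
                                 blood_pressure = NA_real_, spo2 = NA_real_,
                                 breath_rate = NA_real_,
                                 ecg_amp = NA_real_, ecg_rr_cv = NA_real_) {
  tibble(
    patient_id = as.character(patient_id),
    t = cw_posix(cw_time(t)),
    heart_rate = as.numeric(heart_rate),
    body_temp = as.numeric(body_temp),
    blood_pressure = as.numeric(blood_pressure),
    spo2 = as.numeric(spo2),
    breath_rate = as.numeric(breath_rate),
    ecg_amp = as.numeric(ecg_amp),
    ecg_rr_cv = as.numeric(ecg_rr_cv)
  )
}

#' Validate a physiological sample
#'
#' Checks the sample invariants and reports violations as text rather than
#' raising, so that malformed device input can be logged and skipped:
#' all present values must be finite and non-negative, `spo2` must not
#' exceed 100, and at least one sensor field must be present.  An ECG
#' feature is considered present only as the (`ecg_amp`, `ecg_rr_cv`) pair.
#'
#' @param s A one-row data frame (or named list) with the sample columns.
#' @return A character vector of violation descriptions; empty when the
#'   sample satisfies every invariant.
#' @examples
#' validate_sample(physiological_sample("p1", "2026-01-01T08:00:00", spo2 = 105))
#' @export
validate_sample <- function(s) {
  out <- character()
  vals <- lapply(VITAL_SLOTS, function(f) {
    v <- s[[f]]
    if (is.null(v)) NA_real_ else as.numeric(v[[1]])
  })
  names(vals) <- VITAL_SLOTS
  present <- !vapply(vals, is.na, logical(1))
  if (!any(present)) {
    return("no measurements: every sensor field is missing")
  }
  for (f in VITAL_SLOTS[present]) {
    v <- vals[[f]]
    if (!is.finite(v)) out <- c(out, paste0(f, " is not finite"))
    else if (v < 0) out <- c(out, paste0(f, " is negative (", v, ")"))
  }
  if (present[["spo2"]] && is.finite(vals$spo2) && vals$spo2 > 100) {
    out <- c(out, paste0("spo2 exceeds 100% (", vals$spo2, ")"))
  }
  if (xor(present[["ecg_amp"]], present[["ecg_rr_cv"]])) {
    out <- c(out, "incomplete ecg feature: ecg_amp and ecg_rr_cv must both be present")
  }
  out
}

#' Construct a care event
#'
#' A timestamped record that one care procedure was actually performed for
#' a patient: a physiological measurement round, a medication intake, a
#' hygiene procedure, or a feeding.
#'
#' @inheritParams physiological_sample
#' @param category One of `"measurement"`, `"medication"`, `"hygiene"`,
#'   `"feeding"`.
#' @return A one-row tibble with columns `patient_id`, `t`, `category`.
#' @examples
#' care_event("p1", "2026-01-01T12:00:00", "medication")
#' @export
care_event <- function(patient_id, t, category) {
  category <- as.character(category)
  if (!all(category %in% CARE_CATEGORIES)) {
    abort(paste0("unknown care category: ",
                 paste(setdiff(category, CARE_CATEGORIES), collapse = ", ")))
  }
  tibble(patient_id = as.character(patient_id),
         t = cw_posix(cw_time(t)),
         category = category)
}
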