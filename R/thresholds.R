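#' Alarm threshold configuration
#'
#' Criteria for the vital-sign alarm rules.  An alarm fires only on a strict
#' crossing (`>` the upper or `<` the lower criterion); the matching recovery
#' rule requires the value to lie strictly inside the open reference
#' interval, so a value sitting exactly on a criterion fires neither rule.
#'
#' Defaults follow the conventional adult screening criteria used by the
#' rule set: heart rate 60--100 beats/min, systolic blood pressure 90--160
#' mmHg, breath rate 8--24 breaths/min, blood oxygen saturation above 90%,
#' body temperature 35--37 degrees Celsius.  The two ECG feature criteria
#' (normal peak-amplitude range in mV and maximum coefficient of variation
#' of the RR interval) are package defaults for the pluggable ECG
#' abnormality predicate; see [ecg_abnormal()].
#'
#' @param hr_hi,hr_lo Heart-rate criteria, beats/min.
#' @param bp_hi,bp_lo Systolic blood-pressure criteria, mmHg.
#' @param breath_hi,breath_lo Breath-rate criteria, breaths/min.
#' @param spo2_lo Blood-oxygen saturation lower criterion, percent.
#' @param temp_hi,temp_lo Body-temperature criteria, degrees Celsius.
#' @param ecg_amp_range Length-2 numeric, normal ECG peak-amplitude range, mV.
#' @param ecg_rr_cv_max Maximum normal coefficient of variation of the
#'   RR interval (dimensionless).
#' @return An object of class `threshold_config` (a named list).
#' @examples
#' cfg <- default_thresholds()
#' cfg$hr_hi
#' threshold_config(hr_hi = 110)$hr_hi
#' @export
threshold_config <- function(hr_hi = 100, hr_lo = 60,
                             bp_hi = 160, bp_lo = 90,
                             breath_hi = 24, breath_lo = 8,
                             spo2_lo = 90,
                             temp_hi = 37, temp_lo = 35,
                             ecg_amp_range = c(0.5, 2.5),
                             ecg_rr_cv_max = 0.15) {
  cfg <- structure(
    list(hr_hi = hr_hi, hr_lo = hr_lo, bp_hi = bp_hi, bp_lo = bp_lo,
         breath_hi = breath_hi, breath_lo = breath_lo, spo2_lo = spo2_lo,
         temp_hi = temp_hi, temp_lo = temp_lo,
         ecg_amp_range = as.numeric(ecg_amp_range),
         ecg_rr_cv_max = ecg_rr_cv_max),
    class = "threshold_config"
  )
  validate_thresholds(cfg)
  cfg
}

#' @rdname threshold_config
#' @export
default_thresholds <- function() threshold_config()

validate_thresholds <- function(cfg) {
  scalars <- c("hr_hi", "hr_lo", "bp_hi", "bp_lo", "breath_hi", "breath_lo",
               "spo2_lo", "temp_hi", "temp_lo", "ecg_rr_cv_max")
  for (f in scalars) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(paste0("threshold `", f, "` must be a single finite number"))
    }
  }
  if (cfg$hr_lo >= cfg$hr_hi) abort("hr_lo must be < hr_hi")
  if (cfg$bp_lo >= cfg$bp_hi) abort("bp_lo must be < bp_hi")
  if (cfg$breath_lo >= cfg$breath_hi) abort("breath_lo must be < breath_hi")
  if (cfg$temp_lo >= cfg$temp_hi) abort("temp_lo must be < temp_hi")
  if (length(cfg$ecg_amp_range) != 2 || cfg$ecg_amp_range[1] >= cfg$ecg_amp_range[2]) {
    abort("ecg_amp_range must be an increasing pair [lo, hi]")
  }
  invisible(cfg)
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  cat(sprintf("  heart rate      : %g - %g bpm\n", x$hr_lo, x$hr_hi))
  cat(sprintf("  blood pressure  : %g - %g mmHg (systolic)\n", x$bp_lo, x$bp_hi))
  cat(sprintf("  breath rate     : %g - %g /min\n", x$breath_lo, x$breath_hi))
  cat(sprintf("  SpO2            : > %g %%\n", x$spo2_lo))
  cat(sprintf("  body temperature: %g - %g C\n", x$temp_lo, x$temp_hi))
  cat(sprintf("  ECG amplitude   : %g - %g mV, RR CV <= %g\n",
              x$ecg_amp_range[1], x$ecg_amp_range[2], x$ecg_rr_cv_max))
  invisible(x)
}

#' Read and write the monitoring configuration file
#'
#' The YAML configuration mirrors [threshold_config()], [treatment_plan()]
#' and the optional reminder schedule: top-level keys `thresholds`, `plan`
#' (one entry per care category with `required_per_day` and `interval_min`)
#' and `schedule` (a list of `{time, category, message}` entries).
#' `read_config()`/`write_config()` round-trip a configuration exactly.
#'
#' @param path File path of the YAML configuration.
#' @return `read_config()` returns a list with elements `thresholds`
#'   (a `threshold_config`), `plan` (a `treatment_plan`) and `schedule`
#'   (a tibble or `NULL`).
#' @examples
#' p <- tempfile(fileext = ".yml")
#' write_config(p, default_thresholds(), default_plan())
#' identical(read_config(p)$thresholds, default_thresholds())
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("configuration file not found: ", path))
  raw <- yaml::read_yaml(path)
  thr <- if (is.null(raw$thresholds)) default_thresholds() else {
    do.call(threshold_config,
            lapply(raw$thresholds, function(x) as.numeric(unlist(x))))
  }
  plan <- if (is.null(raw$plan)) default_plan() else {
    do.call(treatment_plan, lapply(raw$plan, function(p) {
      as.numeric(c(p$required_per_day, p$interval_min))
    }))
  }
  sched <- NULL
  if (!is.null(raw$schedule)) {
    sched <- reminder_schedule(map_dfr(raw$schedule, as_tibble))
  }
  list(thresholds = thr, plan = plan, schedule = sched)
}

#' @param thresholds A `threshold_config`.
#' @param plan A `treatment_plan`.
#' @param schedule Optional reminder schedule tibble (`time`, `category`,
#'   `message`), see [due_reminders()].
#' @rdname read_config
#' @export
write_config <- function(path, thresholds = default_thresholds(),
                         plan = default_plan(), schedule = NULL) {
  validate_thresholds(thresholds)
  # numbers go out as full-precision decimal strings so that a written
  # configuration reparses to the identical doubles
  out <- list(
    thresholds = lapply(unclass(thresholds), fmt_num),
    plan = purrr::map(stats::setNames(CARE_CATEGORIES, CARE_CATEGORIES),
                      function(cat) list(
                        required_per_day = fmt_num(plan$required[[cat]]),
                        interval_min = fmt_num(plan$interval_min[[cat]])))
  )
  if (!is.null(schedule)) {
    out$schedule <- purrr::pmap(schedule[c("time", "category", "message")], list)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}
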