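#' Knowledge-rule predicates
#'
#' The pure condition parts of the knowledge rules, usable standalone and
#' driven by the inference engine.  Alarm rules fire on a strict crossing
#' of a criterion; a clause whose sensor value is missing is skipped and
#' cannot fire.  Recovery rules are deliberately conservative: they require
#' *all* of their clause values to be present and strictly inside the open
#' reference interval, so an alarm is never cleared on absent evidence and
#' a value sitting exactly on a criterion fires neither the alarm nor the
#' recovery rule (hysteresis gap).
#'
#' Rule identifiers: `K1` abnormal-heart alarm (heart rate, blood pressure,
#' ECG), `K2` its recovery; `K3` abnormal-cardiorespiratory alarm (breath
#' rate, SpO2), `K4` its recovery; `K5` abnormal-body-temperature alarm,
#' `K6` its recovery; `K7`--`K10` the per-category treatment alerts and
#' `R7`--`R10` their recoveries.
#'
#' @param s A physiological sample: one-row data frame or named list with
#'   the [physiological_sample()] columns.
#' @param cfg A [threshold_config()].
#' @return A `rule_result`: list with `rule_id`, `fired` (logical) and
#'   `trigger` (named list of the clause values that decided the outcome;
#'   non-empty whenever `fired` is `TRUE`).
#' @examples
#' eval_heart(physiological_sample("p1", "2026-01-01T08:00:00", heart_rate = 59),
#'            default_thresholds())
#' @name knowledge_rules
NULL

rule_result <- function(rule_id, fired, trigger = list()) {
  structure(list(rule_id = rule_id, fired = fired, trigger = trigger),
            class = "rule_result")
}

#' @export
print.rule_result <- function(x, ...) {
  cat(sprintf("<rule %s> fired: %s\n", x$rule_id, x$fired))
  if (length(x$trigger)) {
    cat("  trigger:", paste(names(x$trigger), unlist(x$trigger),
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# extract one scalar vital from a sample row / named list
sv <- function(s, field) {
  v <- s[[field]]
  if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v[[1]])
}

sample_slots <- function(s) {
  vapply(VITAL_SLOTS, function(f) sv(s, f), numeric(1))
}

# --- scalar condition kernels (shared by the public predicates, the engine
# --- hot loop, and nothing else; the test oracle re-derives these truths
# --- independently) ---------------------------------------------------------

ecg_abnormal_values <- function(amp, rr_cv, cfg) {
  amp < cfg$ecg_amp_range[1] || amp > cfg$ecg_amp_range[2] ||
    rr_cv > cfg$ecg_rr_cv_max
}

heart_alarm_cond <- function(v, cfg, ecg_fn = NULL) {
  (!is.na(v[1]) && (v[1] > cfg$hr_hi || v[1] < cfg$hr_lo)) ||
    (!is.na(v[3]) && (v[3] > cfg$bp_hi || v[3] < cfg$bp_lo)) ||
    (!is.na(v[6]) && !is.na(v[7]) &&
       (if (is.null(ecg_fn)) ecg_abnormal_values(v[6], v[7], cfg)
        else isTRUE(ecg_fn(v[6], v[7]))))
}

heart_recovery_cond <- function(v, cfg, ecg_fn = NULL) {
  !is.na(v[1]) && !is.na(v[3]) && !is.na(v[6]) && !is.na(v[7]) &&
    v[1] > cfg$hr_lo && v[1] < cfg$hr_hi &&
    v[3] > cfg$bp_lo && v[3] < cfg$bp_hi &&
    !(if (is.null(ecg_fn)) ecg_abnormal_values(v[6], v[7], cfg)
      else isTRUE(ecg_fn(v[6], v[7])))
}

cardio_alarm_cond <- function(v, cfg) {
  (!is.na(v[5]) && (v[5] > cfg$breath_hi || v[5] < cfg$breath_lo)) ||
    (!is.na(v[4]) && v[4] < cfg$spo2_lo)
}

cardio_recovery_cond <- function(v, cfg) {
  !is.na(v[5]) && !is.na(v[4]) &&
    v[5] > cfg$breath_lo && v[5] < cfg$breath_hi && v[4] > cfg$spo2_lo
}

temp_alarm_cond <- function(v, cfg) {
  !is.na(v[2]) && (v[2] > cfg$temp_hi || v[2] < cfg$temp_lo)
}

temp_recovery_cond <- function(v, cfg) {
  !is.na(v[2]) && v[2] > cfg$temp_lo && v[2] < cfg$temp_hi
}

# trigger map for a physiological axis: the present clause values
axis_trigger <- function(v, fields) {
  present <- !is.na(v[fields])
  as.list(stats::setNames(v[fields][present], VITAL_SLOTS[fields][present]))
}

AXIS_FIELDS <- list(heart = c(1L, 3L, 6L, 7L), cardio = c(5L, 4L), temp = 2L)

# --- public predicates ------------------------------------------------------

#' @rdname knowledge_rules
#' @export
eval_heart <- function(s, cfg = default_thresholds()) {
  v <- sample_slots(s)
  fired <- heart_alarm_cond(v, cfg)
  trig <- if (fired) {
    out <- list()
    if (!is.na(v[1]) && (v[1] > cfg$hr_hi || v[1] < cfg$hr_lo)) out$heart_rate <- v[[1]]
    if (!is.na(v[3]) && (v[3] > cfg$bp_hi || v[3] < cfg$bp_lo)) out$blood_pressure <- v[[3]]
    if (!is.na(v[6]) && !is.na(v[7]) && ecg_abnormal_values(v[6], v[7], cfg)) {
      out$ecg_amp <- v[[6]]; out$ecg_rr_cv <- v[[7]]
    }
    out
  } else axis_trigger(v, AXIS_FIELDS$heart)
  rule_result("K1", fired, trig)
}

#' @rdname knowledge_rules
#' @export
eval_heart_recovery <- function(s, cfg = default_thresholds()) {
  v <- sample_slots(s)
  rule_result("K2", heart_recovery_cond(v, cfg), axis_trigger(v, AXIS_FIELDS$heart))
}

#' @rdname knowledge_rules
#' @export
eval_cardiorespiratory <- function(s, cfg = default_thresholds()) {
  v <- sample_slots(s)
  fired <- cardio_alarm_cond(v, cfg)
  trig <- if (fired) {
    out <- list()
    if (!is.na(v[5]) && (v[5] > cfg$breath_hi || v[5] < cfg$breath_lo)) out$breath_rate <- v[[5]]
    if (!is.na(v[4]) && v[4] < cfg$spo2_lo) out$spo2 <- v[[4]]
    out
  } else axis_trigger(v, AXIS_FIELDS$cardio)
  rule_result("K3", fired, trig)
}

#' @rdname knowledge_rules
#' @export
eval_cardio_recovery <- function(s, cfg = default_thresholds()) {
  v <- sample_slots(s)
  rule_result("K4", cardio_recovery_cond(v, cfg), axis_trigger(v, AXIS_FIELDS$cardio))
}

#' @rdname knowledge_rules
#' @export
eval_temperature <- function(s, cfg = default_thresholds()) {
  v <- sample_slots(s)
  fired <- temp_alarm_cond(v, cfg)
  rule_result("K5", fired, axis_trigger(v, AXIS_FIELDS$temp))
}

#' @rdname knowledge_rules
#' @export
eval_temp_recovery <- function(s, cfg = default_thresholds()) {
  v <- sample_slots(s)
  rule_result("K6", temp_recovery_cond(v, cfg), axis_trigger(v, AXIS_FIELDS$temp))
}

#' ECG abnormality predicate
#'
#' The default concrete predicate behind the "abnormal magnitudes and
#' cyclic patterns" clause of the heart rule: the ECG is abnormal when the
#' peak amplitude falls outside the configured normal range or the RR
#' interval's coefficient of variation exceeds its maximum.  The engine
#' accepts a replacement predicate via the `ecg_predicate` argument of
#' [run_stream()].
#'
#' @param e A list (or one-row data frame) with `ecg_amp` (or
#'   `peak_amplitude`) and `ecg_rr_cv` (or `rr_cv`).
#' @param cfg A [threshold_config()].
#' @return `TRUE` if the feature pair is abnormal.
#' @examples
#' ecg_abnormal(list(ecg_amp = 3.0, ecg_rr_cv = 0.05))
#' @export
ecg_abnormal <- function(e, cfg = default_thresholds()) {
  amp <- sv(e, "ecg_amp"); if (is.na(amp)) amp <- sv(e, "peak_amplitude")
  rr <- sv(e, "ecg_rr_cv"); if (is.na(rr)) rr <- sv(e, "rr_cv")
  if (is.na(amp) || is.na(rr)) abort("ecg feature requires both amplitude and rr_cv")
  ecg_abnormal_values(amp, rr, cfg)
}

# --- treatment rules --------------------------------------------------------

TREAT_RULE_IDS <- c(measurement = "K7", medication = "K8",
                    hygiene = "K9", feeding = "K10")
TREAT_RECOVERY_IDS <- c(measurement = "R7", medication = "R8",
                        hygiene = "R9", feeding = "R10")

# shared condition: count below daily requirement AND elapsed time since the
# last occurrence strictly above the interval.  With no occurrence on record,
# elapsed time is measured from local midnight of the current day, so a fully
# missed morning routine still alerts.
treat_condition_values <- function(count, required, last_t, interval_sec, t) {
  if (!(count < required)) return(FALSE)
  ref <- if (is.na(last_t)) day_index(t) * 86400 else last_t
  (t - ref) > interval_sec
}

treat_inputs <- function(category, counters, plan, t) {
  if (!category %in% CARE_CATEGORIES) {
    abort(paste0("unknown care category: ", category))
  }
  tnum <- cw_time(t)
  if (as.Date(cw_posix(tnum)) != counters$day) {
    abort("counters refer to a different calendar day than t; call reset_daily() first")
  }
  list(count = counters$count[[category]],
       required = plan$required[[category]],
       last = cw_time(counters$last[[category]]),
       interval = plan$interval_min[[category]] * 60,
       t = tnum)
}

treat_trigger <- function(category, i) {
  list(category = category, count_today = i$count, required_per_day = i$required,
       last_time = if (is.na(i$last)) NA_character_ else format_timestamp(i$last),
       elapsed_min = round((i$t - (if (is.na(i$last)) day_index(i$t) * 86400 else i$last)) / 60, 2),
       interval_min = i$interval / 60)
}

#' Treatment alert and recovery rules
#'
#' `eval_treatment()` is the alert condition for one care category: the
#' day's count is still below the daily requirement while the elapsed time
#' since the most recent occurrence strictly exceeds the planned interval
#' (when no occurrence is on record, elapsed time is measured from local
#' midnight).  `eval_treatment_recovery()` fires, for a category whose
#' alert is active, as soon as that condition no longer holds -- i.e. a
#' care event updated the count or last-occurrence time, or the daily
#' requirement was met.
#'
#' @param category One of `"measurement"`, `"medication"`, `"hygiene"`,
#'   `"feeding"`.
#' @param counters A [treatment_counters()] whose day matches `t`'s
#'   calendar day (reset first, see [reset_daily()]).
#' @param plan A [treatment_plan()].
#' @param t The current time.
#' @inherit knowledge_rules return
#' @examples
#' ctr <- treatment_counters(as.Date("2026-01-01"),
#'   count = c(measurement = 0, medication = 1, hygiene = 0, feeding = 0),
#'   last = stats::setNames(as.POSIXct(c(NA, "2026-01-01 06:00:00", NA, NA),
#'                                     tz = "UTC"),
#'                          c("measurement", "medication", "hygiene", "feeding")))
#' eval_treatment("medication", ctr, default_plan(), "2026-01-01T16:00:00")
#' @export
eval_treatment <- function(category, counters, plan, t) {
  i <- treat_inputs(category, counters, plan, t)
  fired <- treat_condition_values(i$count, i$required, i$last, i$interval, i$t)
  rule_result(TREAT_RULE_IDS[[category]], fired, treat_trigger(category, i))
}

#' @rdname eval_treatment
#' @export
eval_treatment_recovery <- function(category, counters, plan, t) {
  i <- treat_inputs(category, counters, plan, t)
  fired <- !treat_condition_values(i$count, i$required, i$last, i$interval, i$t)
  rule_result(TREAT_RECOVERY_IDS[[category]], fired, treat_trigger(category, i))
}
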