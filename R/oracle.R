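#' Brute-force detection oracle
#'
#' An independent reference detector used to cross-check the inference
#' engine: instead of the event-driven blackboard cycle it computes, per
#' patient, vectorised truth tables of every alarm and recovery condition
#' over the sample stream, walks each situation axis's hysteresis state
#' machine directly, and scans treatment compliance minute by minute over
#' an explicit evaluation grid.  Same semantics, deliberately different
#' code path.
#'
#' `oracle_intervals()` returns the set of (situation, raise, clear)
#' intervals; `oracle_count()` just the physiological/treatment raise
#' totals.
#'
#' @param samples A tibble of [physiological_sample()] rows.
#' @param care_events A tibble of [care_event()] rows (may be `NULL`).
#' @param cfg A [threshold_config()].
#' @param plan A [treatment_plan()].
#' @param tick_interval Evaluation grid spacing in seconds, matching the
#'   engine's tick interval.
#' @return `oracle_intervals()`: a tibble with columns `patient_id`,
#'   `situation`, `raised_at`, `cleared_at` (`NA` when still active at end
#'   of stream).  `oracle_count()`: named numeric with `physiological` and
#'   `treatment` raise counts.
#' @examples
#' gs <- generate_stream(patient_profile("p1"), "2026-01-01T00:00:00",
#'                       "2026-01-01T06:00:00",
#'                       episodes = episode_spec("hypoxia",
#'                                               "2026-01-01T02:00:00", 10),
#'                       seed = 1)
#' oracle_count(gs$samples, NULL)
#' @export
oracle_intervals <- function(samples, care_events = NULL,
                             cfg = default_thresholds(),
                             plan = default_plan(), tick_interval = 60) {
  samples <- if (is.null(samples)) NULL else as_tibble(samples)
  care_events <- if (is.null(care_events) || !nrow(care_events)) NULL else
    as_tibble(care_events)
  pids <- unique(c(if (!is.null(samples)) samples$patient_id,
                   if (!is.null(care_events)) care_events$patient_id))
  out <- map_dfr(pids, function(pid) {
    s <- if (is.null(samples)) NULL else
      samples[samples$patient_id == pid, , drop = FALSE]
    ce <- if (is.null(care_events)) NULL else
      care_events[care_events$patient_id == pid, , drop = FALSE]
    phys <- oracle_phys_intervals(pid, s, cfg)
    treat <- oracle_treat_intervals(pid, s, ce, plan, tick_interval, phys)
    bind_rows(phys, treat)
  })
  if (!nrow(out)) {
    out <- tibble(patient_id = character(), situation = character(),
                  raised_at = cw_posix(numeric()),
                  cleared_at = cw_posix(numeric()))
  }
  out[order(cw_time(out$raised_at), out$patient_id, out$situation), ]
}

#' @rdname oracle_intervals
#' @export
oracle_count <- function(samples, care_events = NULL,
                         cfg = default_thresholds(), plan = default_plan(),
                         tick_interval = 60) {
  iv <- oracle_intervals(samples, care_events, cfg, plan, tick_interval)
  c(physiological = sum(iv$situation %in% unname(PHYS_SITUATIONS)),
    treatment = sum(iv$situation %in% unname(TREAT_SITUATIONS)))
}

# vectorised truth tables + hysteresis walk for the three vital-sign axes
oracle_phys_intervals <- function(pid, s, cfg) {
  empty <- tibble(patient_id = character(), situation = character(),
                  raised_at = cw_posix(numeric()),
                  cleared_at = cw_posix(numeric()))
  if (is.null(s) || !nrow(s)) return(empty)
  s <- s[order(cw_time(s$t)), , drop = FALSE]
  tn <- cw_time(s$t)
  hr <- s$heart_rate; tp <- s$body_temp; bp <- s$blood_pressure
  ox <- s$spo2; br <- s$breath_rate; am <- s$ecg_amp; cv <- s$ecg_rr_cv

  p <- function(x) !is.na(x)
  ecg_abn <- p(am) & p(cv) &
    (am < cfg$ecg_amp_range[1] | am > cfg$ecg_amp_range[2] | cv > cfg$ecg_rr_cv_max)

  alarm <- list(
    heart = (p(hr) & (hr > cfg$hr_hi | hr < cfg$hr_lo)) |
      (p(bp) & (bp > cfg$bp_hi | bp < cfg$bp_lo)) | ecg_abn,
    cardio = (p(br) & (br > cfg$breath_hi | br < cfg$breath_lo)) |
      (p(ox) & ox < cfg$spo2_lo),
    temp = p(tp) & (tp > cfg$temp_hi | tp < cfg$temp_lo)
  )
  recov <- list(
    heart = p(hr) & p(bp) & p(am) & p(cv) &
      hr > cfg$hr_lo & hr < cfg$hr_hi & bp > cfg$bp_lo & bp < cfg$bp_hi & !ecg_abn,
    cardio = p(br) & p(ox) &
      br > cfg$breath_lo & br < cfg$breath_hi & ox > cfg$spo2_lo,
    temp = p(tp) & tp > cfg$temp_lo & tp < cfg$temp_hi
  )

  # the engine holds the last reported value of each sensor, so between
  # reports a clause keeps its previous truth; replicate by forward-filling
  # the per-sample values before computing conditions -- equivalent here
  # because each row already carries the latest values (simulated streams
  # report every sensor).  For partially reported streams, forward-fill:
  ffill <- function(x) {
    if (!anyNA(x) || all(is.na(x))) return(x)
    idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
    out <- x
    out[idx > 0] <- x[idx[idx > 0]]
    out[idx == 0] <- NA
    out
  }
  if (anyNA(hr) || anyNA(tp) || anyNA(bp) || anyNA(ox) || anyNA(br) ||
      anyNA(am) || anyNA(cv)) {
    hr <- ffill(hr); tp <- ffill(tp); bp <- ffill(bp); ox <- ffill(ox)
    br <- ffill(br); am <- ffill(am); cv <- ffill(cv)
    ecg_abn <- p(am) & p(cv) &
      (am < cfg$ecg_amp_range[1] | am > cfg$ecg_amp_range[2] | cv > cfg$ecg_rr_cv_max)
    alarm <- list(
      heart = (p(hr) & (hr > cfg$hr_hi | hr < cfg$hr_lo)) |
        (p(bp) & (bp > cfg$bp_hi | bp < cfg$bp_lo)) | ecg_abn,
      cardio = (p(br) & (br > cfg$breath_hi | br < cfg$breath_lo)) |
        (p(ox) & ox < cfg$spo2_lo),
      temp = p(tp) & (tp > cfg$temp_hi | tp < cfg$temp_lo))
    recov <- list(
      heart = p(hr) & p(bp) & p(am) & p(cv) &
        hr > cfg$hr_lo & hr < cfg$hr_hi & bp > cfg$bp_lo & bp < cfg$bp_hi & !ecg_abn,
      cardio = p(br) & p(ox) &
        br > cfg$breath_lo & br < cfg$breath_hi & ox > cfg$spo2_lo,
      temp = p(tp) & tp > cfg$temp_lo & tp < cfg$temp_hi)
  }

  rows <- list()
  for (ax in c("heart", "cardio", "temp")) {
    a <- alarm[[ax]]; r <- recov[[ax]]
    active <- FALSE
    raised_at <- NA_real_
    for (i in seq_along(tn)) {
      if (!active && isTRUE(a[i])) {
        active <- TRUE
        raised_at <- tn[i]
      } else if (active && isTRUE(r[i])) {
        rows[[length(rows) + 1L]] <- tibble(
          patient_id = pid, situation = PHYS_SITUATIONS[[ax]],
          raised_at = cw_posix(raised_at), cleared_at = cw_posix(tn[i]))
        active <- FALSE
      }
    }
    if (active) {
      rows[[length(rows) + 1L]] <- tibble(
        patient_id = pid, situation = PHYS_SITUATIONS[[ax]],
        raised_at = cw_posix(raised_at), cleared_at = cw_posix(NA_real_))
    }
  }
  if (length(rows)) bind_rows(rows) else empty
}

# explicit evaluation-grid scan for the four treatment categories,
# reproducing the gate: the compliance rules only run at instants when no
# physiological alarm is active (an alarm cleared at exactly t still
# blocks the evaluation at t, since recovery happens after the treatment
# phase of the same cycle)
oracle_treat_intervals <- function(pid, s, ce, plan, tick_interval, phys) {
  empty <- tibble(patient_id = character(), situation = character(),
                  raised_at = cw_posix(numeric()),
                  cleared_at = cw_posix(numeric()))
  st <- if (is.null(s) || !nrow(s)) numeric() else cw_time(s$t)
  ct <- if (is.null(ce) || !nrow(ce)) numeric() else cw_time(ce$t)
  data_t <- c(st, ct)
  if (!length(data_t)) return(empty)
  lo <- min(data_t); hi <- max(data_t)
  ticks <- seq(ceiling(lo / tick_interval) * tick_interval, hi, by = tick_interval)
  grid <- sort(unique(c(data_t, ticks)))

  gate_raise <- cw_time(phys$raised_at)
  gate_clear <- cw_time(phys$cleared_at)
  gated <- function(t) {
    any(gate_raise < t & (is.na(gate_clear) | gate_clear >= t))
  }

  rows <- list()
  for (cat_ in CARE_CATEGORIES) {
    req <- plan$required[[cat_]]
    int_sec <- plan$interval_min[[cat_]] * 60
    cat_t <- if (is.null(ce) || !nrow(ce)) numeric() else
      sort(ct[ce$category == cat_])
    ptr <- 1L
    cnt <- 0
    last <- NA_real_
    day <- day_index(grid[1])
    active <- FALSE
    raised_at <- NA_real_
    for (t in grid) {
      d <- day_index(t)
      if (d > day) { cnt <- 0; day <- d }
      while (ptr <= length(cat_t) && cat_t[ptr] <= t) {
        cnt <- cnt + 1
        last <- cat_t[ptr]
        ptr <- ptr + 1L
      }
      if (gated(t)) next
      ref <- if (is.na(last)) day * 86400 else last
      cond <- cnt < req && (t - ref) > int_sec
      if (!active && cond) {
        active <- TRUE
        raised_at <- t
      } else if (active && !cond) {
        rows[[length(rows) + 1L]] <- tibble(
          patient_id = pid, situation = TREAT_SITUATIONS[[cat_]],
          raised_at = cw_posix(raised_at), cleared_at = cw_posix(t))
        active <- FALSE
      }
    }
    if (active) {
      rows[[length(rows) + 1L]] <- tibble(
        patient_id = pid, situation = TREAT_SITUATIONS[[cat_]],
        raised_at = cw_posix(raised_at), cleared_at = cw_posix(NA_real_))
    }
  }
  if (length(rows)) bind_rows(rows) else empty
}
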