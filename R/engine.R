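#' Blackboard store for one monitored patient
#'
#' The engine's shared store, strictly partitioned into a *domain* side
#' (latest value per sensor, treatment counters, treatment plan) and a
#' *control* side (current process phase, active situations with entry
#' times, and an append-only rule-firing trace).  Control data are never
#' read as measurements.  The store is an environment so that [step()] can
#' update it in place while streaming.
#'
#' @param patient_id Patient identifier.
#' @param plan A [treatment_plan()].
#' @return An object of class `blackboard` (an environment).
#' @seealso [step()], [run_stream()], [blackboard_state()]
#' @examples
#' bb <- blackboard("p1", default_plan())
#' blackboard_state(bb)$control$phase
#' @export
blackboard <- function(patient_id, plan = default_plan()) {
  e <- new.env(parent = emptyenv())
  e$patient_id <- as.character(patient_id)
  e$plan_req <- unname(plan$required[CARE_CATEGORIES])
  e$plan_int <- unname(plan$interval_min[CARE_CATEGORIES]) * 60
  e$clock <- -Inf
  e$latest <- rep(NA_real_, 7L)           # VITAL_SLOTS order
  e$latest_t <- rep(NA_real_, 7L)
  e$day <- NA_real_
  e$cnt <- rep(0, 4L)                     # CARE_CATEGORIES order
  e$last <- rep(NA_real_, 4L)
  e$phys_active <- rep(FALSE, 3L)         # heart, cardio, temp
  e$phys_entered <- rep(NA_real_, 3L)
  e$treat_active <- rep(FALSE, 4L)
  e$treat_entered <- rep(NA_real_, 4L)
  e$phase <- "IDLE"
  e$trace_t <- numeric(256L)
  e$trace_rule <- character(256L)
  e$trace_n <- 0L
  e$realert <- Inf                        # re-alert reminders off by default
  e$next_realert <- rep(Inf, 7L)
  e$ecg_fn <- NULL                        # optional user ECG predicate
  class(e) <- "blackboard"
  e
}

#' @export
print.blackboard <- function(x, ...) {
  cat("<blackboard>", x$patient_id, "\n")
  cat("  phase :", x$phase, "\n")
  act <- active_situations(x)
  cat("  active:", if (length(act)) paste(act, collapse = ", ") else "NORMAL", "\n")
  invisible(x)
}

active_situations <- function(store) {
  c(unname(PHYS_SITUATIONS)[store$phys_active],
    unname(TREAT_SITUATIONS)[store$treat_active])
}

#' Snapshot of a blackboard store
#'
#' Returns the current contents of the store as plain data: the domain
#' partition (latest sample per sensor with its timestamp, treatment
#' counters, plan) and the control partition (phase, situation state with
#' entry times, rule-firing trace).
#'
#' @param store A [blackboard()].
#' @return A list with elements `domain` and `control`.
#' @export
blackboard_state <- function(store) {
  active <- active_situations(store)
  entered <- c(store$phys_entered[store$phys_active],
               store$treat_entered[store$treat_active])
  list(
    domain = list(
      latest = tibble(sensor = VITAL_SLOTS, value = store$latest,
                      t = cw_posix(store$latest_t)),
      counters = treatment_counters(
        if (is.na(store$day)) Sys.Date() else as.Date(store$day, origin = "1970-01-01"),
        count = stats::setNames(store$cnt, CARE_CATEGORIES),
        last = stats::setNames(cw_posix(store$last), CARE_CATEGORIES)),
      plan = treatment_plan(
        measurement = c(store$plan_req[1], store$plan_int[1] / 60),
        medication = c(store$plan_req[2], store$plan_int[2] / 60),
        hygiene = c(store$plan_req[3], store$plan_int[3] / 60),
        feeding = c(store$plan_req[4], store$plan_int[4] / 60))
    ),
    control = list(
      phase = store$phase,
      situation_state = tibble(situation = active, entered_at = cw_posix(entered)),
      trace = tibble(t = cw_posix(store$trace_t[seq_len(store$trace_n)]),
                     rule_id = store$trace_rule[seq_len(store$trace_n)])
    )
  )
}

#' Construct an engine event
#'
#' One unit of input to [step()]: a physiological sample, a care event, or
#' a bare clock tick (which carries only time and lets elapsed-time
#' treatment conditions fire without fresh sensor data).
#'
#' @param kind `"sample"`, `"care"` or `"tick"`.
#' @param t Timestamp.
#' @param patient_id Patient identifier (samples and care events).
#' @param vitals For samples: numeric vector of length 7 in the slot order
#'   `heart_rate, body_temp, blood_pressure, spo2, breath_rate, ecg_amp,
#'   ecg_rr_cv` (`NA` = absent).
#' @param category For care events: the care category.
#' @return A list of class `engine_event`.
#' @export
engine_event <- function(kind, t, patient_id = NULL, vitals = NULL,
                         category = NULL) {
  if (!kind %in% c("sample", "care", "tick")) {
    abort(paste0("unknown event kind: ", kind))
  }
  if (kind == "sample" && (is.null(vitals) || length(vitals) != 7)) {
    abort("sample events need a length-7 vitals vector")
  }
  if (kind == "care" && is.null(category)) abort("care events need a category")
  structure(list(kind = kind, t = cw_time(t), patient_id = patient_id,
                 vitals = if (!is.null(vitals)) as.numeric(vitals),
                 category = category),
            class = "engine_event")
}

# append a rule id to the control-partition trace (grows by doubling)
trace_append <- function(store, t, rule) {
  n <- store$trace_n + 1L
  if (n > length(store$trace_t)) {
    store$trace_t <- c(store$trace_t, numeric(length(store$trace_t)))
    store$trace_rule <- c(store$trace_rule, character(length(store$trace_rule)))
  }
  store$trace_t[n] <- t
  store$trace_rule[n] <- rule
  store$trace_n <- n
}

PHYS_RULE_IDS <- c(heart = "K1", cardio = "K3", temp = "K5")
PHYS_RECOVERY_IDS <- c(heart = "K2", cardio = "K4", temp = "K6")

#' Advance the engine by one event
#'
#' One full reasoning cycle of the three-level rule system.  The strategy
#' level triggers the cycle on every new event.  The control level first
#' opens the *treatment determination* phase -- but only while no
#' physiological alarm is active -- and evaluates the four per-category
#' compliance rules (alert or recovery, depending on the category's
#' state); it then switches to the *physiological reasoning* phase and
#' evaluates the three vital-sign axes in the fixed order heart,
#' cardiorespiratory, body temperature (alarm rule when the axis is quiet,
#' recovery rule when its alarm is active).  Every situation entry emits a
#' `RAISED` alert and every exit a `CLEARED` alert; fired rules are
#' appended to the control-partition trace.
#'
#' Daily treatment counts are reset when the event's calendar day is later
#' than the store's.  Events must arrive in non-decreasing time order.
#'
#' @param store A [blackboard()] for the event's patient.
#' @param ev An [engine_event()].
#' @param cfg A [threshold_config()].
#' @return A list of emitted alert events (each a list with `t`,
#'   `patient_id`, `situation`, `phase`, `detail`); empty when no
#'   situation changed.
#' @examples
#' bb <- blackboard("p1")
#' ev <- engine_event("sample", "2026-01-01T08:00:00", "p1",
#'                    vitals = c(59, NA, NA, NA, NA, NA, NA))
#' step(bb, ev, default_thresholds())
#' @export
step <- function(store, ev, cfg = default_thresholds()) {
  t <- ev$t
  if (t < store$clock) {
    abort(sprintf("out-of-order event: %s arrived after %s",
                  format_timestamp(t), format_timestamp(store$clock)))
  }
  store$clock <- t
  d <- t %/% 86400
  if (is.na(store$day)) {
    store$day <- d
  } else if (d > store$day) {
    store$cnt[] <- 0
    store$day <- d
  }

  kind <- ev$kind
  if (kind == "sample") {
    pid <- ev$patient_id
    if (!is.null(pid) && !is.na(pid) && pid != store$patient_id) {
      abort(sprintf("unknown patient: event for '%s' on store for '%s'",
                    pid, store$patient_id))
    }
    v <- ev$vitals
    p <- which(!is.na(v))
    if (length(p)) {
      store$latest[p] <- v[p]
      store$latest_t[p] <- t
    }
  } else if (kind == "care") {
    ci <- match(ev$category, CARE_CATEGORIES)
    if (is.na(ci)) abort(paste0("unknown care category: ", ev$category))
    if (!is.na(store$last[ci]) && t < store$last[ci]) {
      abort(sprintf("care event at %s precedes recorded last %s time %s",
                    format_timestamp(t), ev$category,
                    format_timestamp(store$last[ci])))
    }
    store$cnt[ci] <- store$cnt[ci] + 1
    store$last[ci] <- t
  } else if (kind != "tick") {
    abort(paste0("unknown event kind: ", kind))
  }

  alerts <- vector("list", 8L)
  na <- 0L
  midnight <- store$day * 86400

  # -- control rule: treatment determination phase, gated on a fully normal
  # -- physiological state ("no alarm occurs")
  if (!(store$phys_active[1L] || store$phys_active[2L] || store$phys_active[3L])) {
    store$phase <- "TREATMENT_DETERMINATION"
    for (i in 1:4) {
      cond <- store$cnt[i] < store$plan_req[i] &&
        (t - (if (is.na(store$last[i])) midnight else store$last[i])) > store$plan_int[i]
      if (store$treat_active[i]) {
        if (!cond) {
          store$treat_active[i] <- FALSE
          trace_append(store, t, TREAT_RECOVERY_IDS[[i]])
          na <- na + 1L
          alerts[[na]] <- list(
            t = t, patient_id = store$patient_id,
            situation = TREAT_SITUATIONS[[i]], phase = "CLEARED",
            detail = treat_detail(store, i, t, midnight))
        }
      } else if (cond) {
        store$treat_active[i] <- TRUE
        store$treat_entered[i] <- t
        store$next_realert[3L + i] <- t + store$realert
        trace_append(store, t, TREAT_RULE_IDS[[i]])
        na <- na + 1L
        alerts[[na]] <- list(
          t = t, patient_id = store$patient_id,
          situation = TREAT_SITUATIONS[[i]], phase = "RAISED",
          detail = treat_detail(store, i, t, midnight))
      }
    }
  }

  # -- control rule: physiological reasoning phase, on the latest features
  store$phase <- "PHYSIOLOGICAL_REASONING"
  v <- store$latest
  for (a in 1:3) {
    if (store$phys_active[a]) {
      rec <- switch(a, heart_recovery_cond(v, cfg, store$ecg_fn),
                    cardio_recovery_cond(v, cfg), temp_recovery_cond(v, cfg))
      if (rec) {
        store$phys_active[a] <- FALSE
        trace_append(store, t, PHYS_RECOVERY_IDS[[a]])
        na <- na + 1L
        alerts[[na]] <- list(
          t = t, patient_id = store$patient_id,
          situation = PHYS_SITUATIONS[[a]], phase = "CLEARED",
          detail = phys_detail(store, a))
      }
    } else {
      alarm <- switch(a, heart_alarm_cond(v, cfg, store$ecg_fn),
                      cardio_alarm_cond(v, cfg), temp_alarm_cond(v, cfg))
      if (alarm) {
        store$phys_active[a] <- TRUE
        store$phys_entered[a] <- t
        store$next_realert[a] <- t + store$realert
        trace_append(store, t, PHYS_RULE_IDS[[a]])
        na <- na + 1L
        alerts[[na]] <- list(
          t = t, patient_id = store$patient_id,
          situation = PHYS_SITUATIONS[[a]], phase = "RAISED",
          detail = phys_detail(store, a))
      }
    }
  }

  # optional re-alert reminders for persisting situations
  if (is.finite(store$realert)) {
    act <- c(store$phys_active, store$treat_active)
    due <- which(act & t >= store$next_realert)
    for (k in due) {
      sit <- if (k <= 3L) PHYS_SITUATIONS[[k]] else TREAT_SITUATIONS[[k - 3L]]
      since <- if (k <= 3L) store$phys_entered[k] else store$treat_entered[k - 3L]
      store$next_realert[k] <- t + store$realert
      na <- na + 1L
      alerts[[na]] <- list(
        t = t, patient_id = store$patient_id, situation = sit,
        phase = "REMINDER",
        detail = list(active_since = format_timestamp(since)))
    }
  }

  if (na == 0L) list() else alerts[seq_len(na)]
}

# alert detail payloads; the video reference is a placeholder standing in
# for the live-video attachment of the full monitoring system
phys_detail <- function(store, axis) {
  fields <- AXIS_FIELDS[[axis]]
  present <- !is.na(store$latest[fields])
  d <- as.list(stats::setNames(store$latest[fields][present],
                               VITAL_SLOTS[fields][present]))
  d$video_ref <- paste0("video://", store$patient_id)
  d
}

treat_detail <- function(store, i, t, midnight) {
  ref <- if (is.na(store$last[i])) midnight else store$last[i]
  list(category = CARE_CATEGORIES[[i]],
       count_today = store$cnt[i],
       required_per_day = store$plan_req[i],
       last_time = if (is.na(store$last[i])) NA_character_ else
         format_timestamp(store$last[i]),
       elapsed_min = round((t - ref) / 60, 2),
       interval_min = store$plan_int[i] / 60,
       video_ref = paste0("video://", store$patient_id))
}

# helper used by both the stream driver and the detection oracle is *not*
# shared: each computes its own tick grid so they stay independent.
stream_tick_times <- function(t_min, t_max, tick_interval, existing) {
  if (!is.finite(t_min) || t_max <= t_min) return(numeric())
  ticks <- seq(ceiling(t_min / tick_interval) * tick_interval, t_max,
               by = tick_interval)
  ticks[!(ticks %in% existing)]
}

#' Run the engine over a batch of events
#'
#' Drives [step()] over a time-sorted stream of samples and care events,
#' auto-inserting bare clock ticks every `tick_interval` seconds so that
#' elapsed-time treatment conditions can fire without fresh sensor data.
#' Multi-patient streams are supported; each patient gets its own
#' blackboard.  At equal timestamps care events are processed before
#' samples, and samples before ticks.  The result is deterministic for
#' fixed inputs.
#'
#' @param events A tibble of events as produced by [engine_events()]:
#'   columns `kind`, `patient_id`, `t`, the seven vital columns and
#'   `category`.  Alternatively pass `samples`/`care_events` to
#'   [monitor_stream()].
#' @param cfg A [threshold_config()].
#' @param plan A [treatment_plan()].
#' @param tick_interval Tick spacing in seconds (default 60).
#' @param schedule Optional [reminder_schedule()]; due entries are emitted
#'   as patient-facing `REMINDER` alerts.
#' @param realert_interval Optional seconds between repeated `REMINDER`
#'   notifications for a persisting situation (default off).
#' @param ecg_predicate Optional replacement ECG abnormality predicate,
#'   `function(amp, rr_cv) -> logical`.
#' @return A `carewatch_run` object: list with `alerts` (tibble: `t`,
#'   `patient_id`, `situation`, `phase`, `detail` list-column), `counts`
#'   (per-situation `RAISED` counts, see [situation_report()]), `trace`
#'   (rule-firing log tibble) and `n_events`.
#' @examples
#' sam <- physiological_sample("p1", "2026-01-01T08:00:00", heart_rate = 130)
#' run <- monitor_stream(sam)
#' tidy(run)
#' @export
run_stream <- function(events, cfg = default_thresholds(), plan = default_plan(),
                       tick_interval = 60, schedule = NULL,
                       realert_interval = NULL, ecg_predicate = NULL) {
  events <- as_tibble(events)
  needed <- c("kind", "patient_id", "t")
  if (!all(needed %in% names(events))) {
    abort("events need columns kind, patient_id, t (see engine_events())")
  }
  for (f in VITAL_SLOTS) if (is.null(events[[f]])) events[[f]] <- NA_real_
  if (is.null(events[["category"]])) events[["category"]] <- NA_character_

  patients <- unique(events$patient_id)
  all_alerts <- list()
  all_trace <- list()
  n_events_total <- 0L

  for (pid in patients) {
    sub <- events[events$patient_id == pid, , drop = FALSE]
    tn <- cw_time(sub$t)
    prio <- match(sub$kind, c("care", "sample", "tick"))
    ord <- order(tn, prio)
    tn <- tn[ord]
    kinds <- sub$kind[ord]
    cats <- sub$category[ord]
    V <- rbind(sub$heart_rate, sub$body_temp, sub$blood_pressure, sub$spo2,
               sub$breath_rate, sub$ecg_amp, sub$ecg_rr_cv)[, ord, drop = FALSE]

    ticks <- stream_tick_times(min(tn), max(tn), tick_interval, tn)
    if (length(ticks)) {
      tn2 <- c(tn, ticks)
      kinds <- c(kinds, rep("tick", length(ticks)))
      cats <- c(cats, rep(NA_character_, length(ticks)))
      V <- cbind(V, matrix(NA_real_, 7L, length(ticks)))
      ord2 <- order(tn2, c(rep(0L, length(tn)), rep(1L, length(ticks))))
      tn <- tn2[ord2]; kinds <- kinds[ord2]; cats <- cats[ord2]
      V <- V[, ord2, drop = FALSE]
    }

    store <- blackboard(pid, plan)
    if (!is.null(realert_interval)) store$realert <- realert_interval
    store$ecg_fn <- ecg_predicate

    acc <- vector("list", 64L)
    nacc <- 0L
    n <- length(tn)
    for (i in seq_len(n)) {
      ev <- list(kind = kinds[i], t = tn[i], patient_id = NULL,
                 vitals = V[, i], category = cats[i])
      out <- tryCatch(step(store, ev, cfg), error = function(e) {
        abort(sprintf("event %d for patient %s (%s): %s", i, pid,
                      format_timestamp(tn[i]), conditionMessage(e)))
      })
      if (length(out)) {
        for (al in out) {
          nacc <- nacc + 1L
          if (nacc > length(acc)) acc <- c(acc, vector("list", length(acc)))
          acc[[nacc]] <- al
        }
      }
    }
    n_events_total <- n_events_total + n

    if (nacc) all_alerts[[pid]] <- acc[seq_len(nacc)]

    # patient-facing schedule reminders over the stream's span
    if (!is.null(schedule) && n > 1L) {
      rem <- due_reminders(schedule, tn[1], tn[n])
      if (nrow(rem)) {
        all_alerts[[paste0(pid, ".sched")]] <- purrr::pmap(
          list(cw_time(rem$t), rem$category, rem$message),
          function(tt, cc, mm) list(t = tt, patient_id = pid,
                                    situation = TREAT_SITUATIONS[[cc]],
                                    phase = "REMINDER",
                                    detail = list(category = cc, message = mm)))
      }
    }

    st <- blackboard_state(store)
    tr <- st$control$trace
    tr$patient_id <- pid
    all_trace[[pid]] <- tr
  }

  flat <- unlist(all_alerts, recursive = FALSE, use.names = FALSE)
  alerts <- alert_tibble(flat)
  trace <- if (length(all_trace)) bind_rows(all_trace) else
    tibble(t = cw_posix(numeric()), rule_id = character(),
           patient_id = character())

  structure(
    list(alerts = alerts, counts = situation_report(alerts), trace = trace,
         n_events = n_events_total, patients = patients,
         cfg = cfg, plan = plan, tick_interval = tick_interval),
    class = "carewatch_run")
}

alert_tibble <- function(flat) {
  if (is.null(flat) || !length(flat)) {
    return(tibble(t = cw_posix(numeric()), patient_id = character(),
                  situation = character(), phase = character(),
                  detail = list()))
  }
  out <- tibble(
    t = cw_posix(map_dbl(flat, "t")),
    patient_id = map_chr(flat, "patient_id"),
    situation = map_chr(flat, "situation"),
    phase = map_chr(flat, "phase"),
    detail = map(flat, "detail")
  )
  out[order(out$t, out$patient_id, match(out$phase, c("CLEARED", "RAISED", "REMINDER"))), ]
}

#' Monitor tidy sample and care-event tables
#'
#' Convenience wrapper: binds samples and care events into an engine event
#' stream (see [engine_events()]) and calls [run_stream()].
#'
#' @param samples A tibble of [physiological_sample()] rows.
#' @param care_events A tibble of [care_event()] rows (optional).
#' @inheritParams run_stream
#' @inherit run_stream return
#' @export
monitor_stream <- function(samples, care_events = NULL, ...) {
  run_stream(engine_events(samples, care_events), ...)
}

#' Combine samples and care events into an engine event stream
#'
#' @inheritParams monitor_stream
#' @return A tibble with one row per event, sorted by time (care events
#'   before samples at equal timestamps), ready for [run_stream()].
#' @export
engine_events <- function(samples = NULL, care_events = NULL) {
  parts <- list()
  if (!is.null(samples) && nrow(samples)) {
    s <- as_tibble(samples)
    s$kind <- "sample"
    s$category <- NA_character_
    parts$samples <- s
  }
  if (!is.null(care_events) && nrow(care_events)) {
    ce <- as_tibble(care_events)
    ce$kind <- "care"
    parts$care <- ce
  }
  if (!length(parts)) {
    return(tibble(kind = character(), patient_id = character(),
                  t = cw_posix(numeric()), category = character()))
  }
  out <- bind_rows(parts)
  for (f in VITAL_SLOTS) if (is.null(out[[f]])) out[[f]] <- NA_real_
  prio <- match(out$kind, c("care", "sample"))
  out <- out[order(cw_time(out$t), prio), ]
  out[, c("kind", "patient_id", "t", VITAL_SLOTS, "category")]
}

#' @export
print.carewatch_run <- function(x, ...) {
  cat("<carewatch_run>", length(x$patients), "patient(s),",
      x$n_events, "events\n")
  cat("  alerts:", nrow(x$alerts), "(",
      sum(x$alerts$phase == "RAISED"), "RAISED,",
      sum(x$alerts$phase == "CLEARED"), "CLEARED )\n")
  rep_ <- x$counts
  cat(sprintf("  physiological alarms raised: %d\n",
              attr(rep_, "physiological_total")))
  cat(sprintf("  treatment alerts raised    : %d\n",
              attr(rep_, "treatment_total")))
  invisible(x)
}

#' Per-situation counts of raised alarms and alerts
#'
#' Counts `RAISED` events per situation over an alert log, together with
#' the physiological total (the three alarm situations) and the treatment
#' total (the four alert situations), attached as attributes
#' `physiological_total` and `treatment_total`.
#'
#' @param log A `carewatch_run`, or an alert tibble with columns
#'   `situation` and `phase`.
#' @return A tibble with columns `situation` and `n_raised` (one row per
#'   situation, all seven always present).
#' @examples
#' run <- monitor_stream(physiological_sample("p1", "2026-01-01T08:00:00",
#'                                            heart_rate = 130))
#' situation_report(run)
#' @export
situation_report <- function(log) {
  alerts <- if (inherits(log, "carewatch_run")) log$alerts else as_tibble(log)
  sits <- c(unname(PHYS_SITUATIONS), unname(TREAT_SITUATIONS))
  raised <- alerts[alerts$phase == "RAISED", , drop = FALSE]
  n <- vapply(sits, function(s) sum(raised$situation == s), numeric(1))
  out <- tibble(situation = sits, n_raised = unname(n))
  attr(out, "physiological_total") <- sum(n[unname(PHYS_SITUATIONS)])
  attr(out, "treatment_total") <- sum(n[unname(TREAT_SITUATIONS)])
  out
}
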