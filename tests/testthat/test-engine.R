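sample_ev <- function(t, hr = NA, temp = NA, bp = NA, spo2 = NA, br = NA,
                      amp = NA, cv = NA) {
  engine_event("sample", t, "p1", vitals = c(hr, temp, bp, spo2, br, amp, cv))
}

test_that("a bradycardic sample raises the heart alarm after the treatment phase", {
  bb <- blackboard("p1", treatment_plan(medication = c(2, 120)))
  # prime the clock early on the day; medication never given
  expect_length(step(bb, engine_event("tick", "2026-01-05T00:00:00")), 0)
  out <- step(bb, sample_ev("2026-01-05T08:00:00", hr = 59, bp = 120,
                            amp = 1, cv = 0.05))
  expect_length(out, 2)
  # treatment determination ran first (overdue medication), then the alarm
  expect_equal(out[[1]]$situation, "UNCHARACTERISTIC_MEDICATION")
  expect_equal(out[[1]]$phase, "RAISED")
  expect_equal(out[[2]]$situation, "ABNORMAL_HEART")
  expect_equal(out[[2]]$phase, "RAISED")
  expect_equal(out[[2]]$detail$heart_rate, 59)
  st <- blackboard_state(bb)
  expect_true(all(c("K8", "K1") %in% st$control$trace$rule_id))
  expect_lt(which(st$control$trace$rule_id == "K8"),
            which(st$control$trace$rule_id == "K1"))
})

test_that("no treatment alert is emitted while a physiological alarm is active", {
  bb <- blackboard("p1", treatment_plan(medication = c(2, 120)))
  step(bb, engine_event("tick", "2026-01-05T00:00:00"))
  out <- step(bb, sample_ev("2026-01-05T00:30:00", hr = 55, bp = 120,
                            amp = 1, cv = 0.05))
  expect_equal(purrr::map_chr(out, "situation"), "ABNORMAL_HEART")
  # medication becomes overdue at 02:00+, but the alarm gates the phase
  out <- step(bb, engine_event("care", "2026-01-05T05:00:00", "p1",
                               category = "hygiene"))
  expect_length(out, 0)
  out <- step(bb, engine_event("tick", "2026-01-05T06:00:00"))
  expect_length(out, 0)
  # recovery clears the alarm; the gate is still closed in the same cycle
  out <- step(bb, sample_ev("2026-01-05T06:30:00", hr = 75, bp = 120,
                            amp = 1, cv = 0.05))
  expect_equal(purrr::map_chr(out, "situation"), "ABNORMAL_HEART")
  expect_equal(purrr::map_chr(out, "phase"), "CLEARED")
  # the deferred treatment alert fires on the first cycle after clearing
  out <- step(bb, engine_event("tick", "2026-01-05T06:31:00"))
  expect_equal(purrr::map_chr(out, "situation"), "UNCHARACTERISTIC_MEDICATION")
  expect_equal(purrr::map_chr(out, "phase"), "RAISED")
})

test_that("events must arrive in non-decreasing time order", {
  bb <- blackboard("p1")
  step(bb, sample_ev("2026-01-05T08:00:00", hr = 72))
  expect_error(step(bb, sample_ev("2026-01-05T07:59:00", hr = 72)),
               "out-of-order")
  expect_error(step(bb, engine_event("care", "2026-01-05T09:00:00", "p1",
                                     category = "nap")),
               "unknown care category")
  ev <- sample_ev("2026-01-05T09:00:00", hr = 72)
  ev$patient_id <- "someone-else"
  expect_error(step(bb, ev), "unknown patient")
})

test_that("an injected hypoxia episode yields exactly one raise/clear pair", {
  gs <- generate_stream(patient_profile("p1"), DAY1, DAY1 + 6 * 3600,
                        episodes = episode_spec("hypoxia", DAY1 + 2 * 3600, 5),
                        seed = 21)
  run <- monitor_stream(gs$samples)
  al <- tidy(run)
  expect_equal(nrow(al), 2)
  expect_equal(al$situation, rep("ABNORMAL_CARDIORESPIRATORY", 2))
  expect_equal(al$phase, c("RAISED", "CLEARED"))
  expect_equal(al$t[1], ts("2026-01-05T02:00:00"))
  expect_equal(al$t[2], ts("2026-01-05T02:05:00"))
})

test_that("empty streams produce an empty alert log", {
  run <- run_stream(engine_events(NULL, NULL))
  expect_equal(nrow(run$alerts), 0)
  expect_equal(run$n_events, 0L)
  expect_equal(attr(run$counts, "physiological_total"), 0)
})

test_that("a never-given medication raises one de-duplicated alert per day", {
  plan <- treatment_plan(measurement = c(0, 540), medication = c(2, 240),
                         hygiene = c(0, 540), feeding = c(0, 540))
  events <- tibble::tibble(kind = "tick", patient_id = "p1",
                           t = c(ts("2026-01-05T00:00:00"),
                                 ts("2026-01-06T00:00:00")))
  run <- run_stream(events, plan = plan)
  raised <- run$alerts[run$alerts$phase == "RAISED", ]
  expect_equal(nrow(raised), 1)
  expect_equal(raised$situation, "UNCHARACTERISTIC_MEDICATION")
  # with no last time on record, elapsed counts from midnight: > 4 h
  expect_equal(raised$t, ts("2026-01-05T04:01:00"))

  # independent scan of the alert condition over the tick grid
  ticks <- seq(as.numeric(ts("2026-01-05T00:00:00")),
               as.numeric(ts("2026-01-06T00:00:00")), by = 60)
  cond <- (ticks - (ticks %/% 86400) * 86400) > 240 * 60
  expect_equal(sum(diff(c(FALSE, cond)) == 1), 1)
  expect_equal(ticks[which(cond)[1]], as.numeric(raised$t))
})

test_that("situation reports count raises per situation with totals", {
  al <- tibble::tibble(
    t = as.POSIXct(DAY1 + 1:9 * 60, origin = "1970-01-01", tz = "UTC"),
    patient_id = "p1",
    situation = c(rep("ABNORMAL_HEART", 3), rep("UNCHARACTERISTIC_MEDICATION", 4),
                  rep("ABNORMAL_HEART", 2)),
    phase = c("RAISED", "CLEARED", "RAISED", "RAISED", "CLEARED", "RAISED",
              "CLEARED", "RAISED", "CLEARED"),
    detail = vector("list", 9))
  rep_ <- situation_report(al)
  expect_equal(rep_$n_raised[rep_$situation == "ABNORMAL_HEART"], 3)
  expect_equal(attr(rep_, "physiological_total"), 3)
  expect_equal(attr(rep_, "treatment_total"), 2)
  expect_equal(sum(rep_$n_raised), sum(al$phase == "RAISED"))
})

test_that("raising the upper heart criterion never adds heart alarms", {
  gs <- generate_stream(patient_profile("p1"), DAY1, DAY1 + 4 * 3600,
                        episodes = list(
                          episode_spec("heart_high", DAY1 + 3600, 10),
                          episode_spec("fever", DAY1 + 2 * 3600, 10)),
                        seed = 31)
  counts <- vapply(c(100, 103, 106, 200), function(hi) {
    run <- monitor_stream(gs$samples, cfg = threshold_config(hr_hi = hi))
    sum(run$alerts$situation == "ABNORMAL_HEART" & run$alerts$phase == "RAISED")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 1)
})

test_that("identical inputs give identical alert logs and traces", {
  sc <- random_scenario(17)
  r1 <- monitor_stream(sc$samples, sc$care_events)
  r2 <- monitor_stream(sc$samples, sc$care_events)
  expect_identical(r1$alerts, r2$alerts)
  expect_identical(r1$trace, r2$trace)
})

test_that("scheduled reminders are emitted as REMINDER events", {
  sched <- reminder_schedule(data.frame(time = "02:00", category = "medication",
                                        message = "take pills"))
  gs <- generate_stream(patient_profile("p1"), DAY1, DAY1 + 4 * 3600, seed = 4)
  run <- monitor_stream(gs$samples, schedule = sched)
  rem <- run$alerts[run$alerts$phase == "REMINDER", ]
  expect_equal(nrow(rem), 1)
  expect_equal(rem$t, ts("2026-01-05T02:00:00"))
  expect_equal(rem$detail[[1]]$message, "take pills")
})
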