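# Independent truth-table oracle for the vital-sign rules, coded straight
# from the printed criteria (strict inequalities, open recovery intervals).
brute_heart_alarm <- function(hr, bp, amp, cv, cfg) {
  ecg_bad <- !is.na(amp) && !is.na(cv) &&
    (amp < cfg$ecg_amp_range[1] || amp > cfg$ecg_amp_range[2] ||
       cv > cfg$ecg_rr_cv_max)
  (!is.na(hr) && (hr > 100 || hr < 60)) ||
    (!is.na(bp) && (bp > 160 || bp < 90)) || ecg_bad
}
brute_heart_recovery <- function(hr, bp, amp, cv, cfg) {
  !is.na(hr) && !is.na(bp) && !is.na(amp) && !is.na(cv) &&
    (60 < hr && hr < 100) && (90 < bp && bp < 160) &&
    !(amp < cfg$ecg_amp_range[1] || amp > cfg$ecg_amp_range[2] ||
        cv > cfg$ecg_rr_cv_max)
}

test_that("heart rule matches spec examples and skips missing clauses", {
  cfg <- default_thresholds()
  r <- eval_heart(nominal_sample(heart_rate = 59), cfg)
  expect_true(r$fired)
  expect_equal(r$trigger$heart_rate, 59)

  # boundary values fire nothing (strict inequalities)
  r <- eval_heart(nominal_sample(heart_rate = 100, blood_pressure = 160), cfg)
  expect_false(r$fired)

  r <- eval_heart(nominal_sample(heart_rate = 72, blood_pressure = 165), cfg)
  expect_true(r$fired)
  expect_equal(r$trigger$blood_pressure, 165)

  # a missing sensor cannot fire its clause
  s <- physiological_sample("p1", "2026-01-05T08:00:00", body_temp = 40)
  expect_false(eval_heart(s, cfg)$fired)
})

test_that("heart recovery requires all three clauses present and inside", {
  cfg <- default_thresholds()
  expect_true(eval_heart_recovery(nominal_sample(heart_rate = 75,
                                                 blood_pressure = 120), cfg)$fired)
  no_ecg <- nominal_sample(heart_rate = 75, blood_pressure = 120,
                           ecg_amp = NA, ecg_rr_cv = NA)
  expect_false(eval_heart_recovery(no_ecg, cfg)$fired)
  expect_false(eval_heart_recovery(nominal_sample(heart_rate = 100), cfg)$fired)
})

test_that("cardiorespiratory and temperature rules respect the hysteresis gap", {
  cfg <- default_thresholds()
  expect_true(eval_cardiorespiratory(nominal_sample(spo2 = 89), cfg)$fired)
  expect_true(eval_cardio_recovery(nominal_sample(breath_rate = 16,
                                                  spo2 = 95), cfg)$fired)
  # exactly 90%: neither alarm nor recovery
  at90 <- nominal_sample(spo2 = 90)
  expect_false(eval_cardiorespiratory(at90, cfg)$fired)
  expect_false(eval_cardio_recovery(at90, cfg)$fired)

  expect_true(eval_temperature(nominal_sample(body_temp = 37.5), cfg)$fired)
  expect_true(eval_temp_recovery(nominal_sample(body_temp = 36.0), cfg)$fired)
  at37 <- nominal_sample(body_temp = 37.0)
  expect_false(eval_temperature(at37, cfg)$fired)
  expect_false(eval_temp_recovery(at37, cfg)$fired)
})

test_that("ecg abnormality predicate uses the configured feature ranges", {
  expect_false(ecg_abnormal(list(ecg_amp = 1.0, ecg_rr_cv = 0.05)))
  expect_true(ecg_abnormal(list(ecg_amp = 3.0, ecg_rr_cv = 0.05)))
  expect_true(ecg_abnormal(list(ecg_amp = 1.0, ecg_rr_cv = 0.2)))
  expect_true(ecg_abnormal(list(peak_amplitude = 0.2, rr_cv = 0.05)))
  expect_error(ecg_abnormal(list(ecg_amp = 1.0)), "rr_cv")
})

test_that("rule predicates agree with a brute-force truth table", {
  cfg <- default_thresholds()
  grid_hr <- seq(58, 102, by = 0.5)
  grid_bp <- seq(88, 162, by = 0.5)
  withr::local_seed(99)
  for (i in 1:400) {
    hr <- sample(c(sample(grid_hr, 1), NA), 1, prob = c(0.9, 0.1))
    bp <- sample(c(sample(grid_bp, 1), NA), 1, prob = c(0.9, 0.1))
    amp <- sample(c(runif(1, 0.3, 2.7), NA), 1, prob = c(0.9, 0.1))
    cv <- sample(c(runif(1, 0.1, 0.2), NA), 1, prob = c(0.9, 0.1))
    s <- physiological_sample("p", "2026-01-05T08:00:00", heart_rate = hr,
                              blood_pressure = bp, ecg_amp = amp,
                              ecg_rr_cv = cv)
    expect_equal(eval_heart(s, cfg)$fired,
                 brute_heart_alarm(hr, bp, amp, cv, cfg))
    expect_equal(eval_heart_recovery(s, cfg)$fired,
                 brute_heart_recovery(hr, bp, amp, cv, cfg))
  }
  for (b in seq(6, 26, by = 0.25)) {
    for (o in c(88, 89.75, 90, 90.25, 95)) {
      s <- physiological_sample("p", "2026-01-05T08:00:00", breath_rate = b,
                                spo2 = o)
      expect_equal(eval_cardiorespiratory(s, cfg)$fired,
                   (b > 24 || b < 8) || o < 90)
      expect_equal(eval_cardio_recovery(s, cfg)$fired,
                   (8 < b && b < 24) && o > 90)
    }
  }
  for (tv in seq(33, 39, by = 0.05)) {
    s <- physiological_sample("p", "2026-01-05T08:00:00", body_temp = tv)
    expect_equal(eval_temperature(s, cfg)$fired, tv > 37 || tv < 35)
    expect_equal(eval_temp_recovery(s, cfg)$fired, 35 < tv && tv < 37)
  }
})

test_that("an alarm rule and its recovery rule never both fire", {
  cfg <- default_thresholds()
  withr::local_seed(7)
  for (i in 1:300) {
    s <- physiological_sample(
      "p", "2026-01-05T08:00:00",
      heart_rate = runif(1, 50, 110), body_temp = runif(1, 34, 38.5),
      blood_pressure = runif(1, 80, 170), spo2 = runif(1, 85, 100),
      breath_rate = runif(1, 5, 28), ecg_amp = runif(1, 0.3, 2.8),
      ecg_rr_cv = runif(1, 0, 0.25))
    expect_false(eval_heart(s, cfg)$fired && eval_heart_recovery(s, cfg)$fired)
    expect_false(eval_cardiorespiratory(s, cfg)$fired &&
                   eval_cardio_recovery(s, cfg)$fired)
    expect_false(eval_temperature(s, cfg)$fired &&
                   eval_temp_recovery(s, cfg)$fired)
  }
})

test_that("treatment rules fire on unmet count plus elapsed interval", {
  plan <- treatment_plan(medication = c(3, 240))
  last <- stats::setNames(
    as.POSIXct(c(NA, "2026-01-05 06:00:00", NA, NA), tz = "UTC"),
    c("measurement", "medication", "hygiene", "feeding"))
  ctr <- treatment_counters(as.Date("2026-01-05"),
                            count = c(measurement = 0, medication = 1,
                                      hygiene = 0, feeding = 0),
                            last = last)
  # 5h elapsed > 4h interval and 1 < 3
  r <- eval_treatment("medication", ctr, plan, "2026-01-05T11:00:00")
  expect_true(r$fired)
  expect_equal(r$rule_id, "K8")

  # count met: never fires regardless of elapsed time
  ctr2 <- ctr; ctr2$count[["medication"]] <- 3
  expect_false(eval_treatment("medication", ctr2, plan, "2026-01-05T23:00:00")$fired)

  # elapsed exactly equal to the interval: strict, no fire
  expect_false(eval_treatment("medication", ctr, plan, "2026-01-05T10:00:00")$fired)

  # no occurrence on record: elapsed measured from local midnight
  expect_false(eval_treatment("hygiene", ctr, default_plan(), "2026-01-05T08:00:00")$fired)
  expect_true(eval_treatment("hygiene", ctr, default_plan(), "2026-01-05T09:01:00")$fired)

  expect_error(eval_treatment("bathing", ctr, plan, "2026-01-05T10:00:00"),
               "unknown care category")
})

test_that("treatment recovery is the exact negation of the alert condition", {
  plan <- default_plan()
  withr::local_seed(11)
  for (i in 1:200) {
    cnt <- sample(0:4, 4, replace = TRUE)
    lastn <- DAY1 + sample(c(NA, sample(0:43200, 3)), 4, replace = TRUE)
    ctr <- treatment_counters(
      as.Date("2026-01-05"),
      count = stats::setNames(cnt, c("measurement", "medication", "hygiene",
                                     "feeding")),
      last = stats::setNames(as.POSIXct(lastn, origin = "1970-01-01",
                                        tz = "UTC"),
                             c("measurement", "medication", "hygiene",
                               "feeding")))
    t <- DAY1 + sample(43200:86000, 1)
    for (cat_ in c("measurement", "medication", "hygiene", "feeding")) {
      k <- eval_treatment(cat_, ctr, plan, t)$fired
      r <- eval_treatment_recovery(cat_, ctr, plan, t)$fired
      expect_equal(r, !k)
    }
  }
})
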