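test_that("baseline streams stay inside the alarm-free region", {
  gs <- generate_stream(patient_profile("p1"), DAY1, DAY1 + 86400, seed = 1)
  expect_equal(nrow(gs$samples), 1440)
  expect_equal(nrow(gs$ground_truth), 0)
  cfg <- default_thresholds()
  s <- gs$samples
  expect_true(all(s$heart_rate > cfg$hr_lo & s$heart_rate < cfg$hr_hi))
  expect_true(all(s$blood_pressure > cfg$bp_lo & s$blood_pressure < cfg$bp_hi))
  expect_true(all(s$spo2 > cfg$spo2_lo & s$spo2 <= 100))
  expect_true(all(s$breath_rate > cfg$breath_lo & s$breath_rate < cfg$breath_hi))
  expect_true(all(s$body_temp > cfg$temp_lo & s$body_temp < cfg$temp_hi))
  # with no care obligations, a baseline stream raises nothing at all
  none <- treatment_plan(measurement = c(0, 540), medication = c(0, 540),
                         hygiene = c(0, 540), feeding = c(0, 540))
  run <- monitor_stream(s, plan = none)
  expect_equal(nrow(run$alerts), 0)
})

test_that("streams are seed-deterministic and seed-sensitive", {
  a <- generate_stream(patient_profile("p1"), DAY1, DAY1 + 3600, seed = 1)
  b <- generate_stream(patient_profile("p1"), DAY1, DAY1 + 3600, seed = 1)
  c <- generate_stream(patient_profile("p1"), DAY1, DAY1 + 3600, seed = 2)
  expect_identical(a$samples, b$samples)
  expect_false(isTRUE(all.equal(a$samples$heart_rate, c$samples$heart_rate)))
})

test_that("episodes drive the targeted vital strictly past its criterion", {
  ep <- episode_spec("hypoxia", DAY1 + 3600, 10)
  gs <- generate_stream(patient_profile("p1"), DAY1, DAY1 + 7200,
                        episodes = ep, seed = 5)
  inside <- gs$samples$t >= ts("2026-01-05T01:00:00") &
    gs$samples$t < ts("2026-01-05T01:10:00")
  expect_true(all(gs$samples$spo2[inside] < 90))
  expect_true(all(gs$samples$spo2[!inside] > 90))
  expect_equal(gs$ground_truth$situation, "ABNORMAL_CARDIORESPIRATORY")
  expect_equal(gs$ground_truth$magnitude, 0.05 * 90)

  expect_error(generate_stream(
    patient_profile("p1"), DAY1, DAY1 + 7200, seed = 1,
    episodes = list(episode_spec("hypoxia", DAY1 + 600, 30),
                    episode_spec("tachypnea", DAY1 + 1200, 30))),
    "overlapping")
  expect_error(generate_stream(patient_profile("p1"), DAY1, DAY1 + 3600,
                               episodes = episode_spec("fever", DAY1 + 3000, 60),
                               seed = 1),
               "within")
})

test_that("care-event generation is compliant unless a slot is missed", {
  gc <- generate_care_events(default_plan(), 3, seed = 9, patient_id = "p1")
  expect_equal(nrow(gc$care_events), 3 * 4 * 3)
  run <- run_stream(engine_events(care_events = gc$care_events))
  expect_equal(nrow(run$alerts), 0)

  gm <- generate_care_events(default_plan(), 2,
                             missed = data.frame(day = 1,
                                                 category = "feeding"),
                             seed = 9, patient_id = "p1")
  expect_equal(nrow(gm$care_events), 2 * 4 * 3 - 1)
  expect_equal(gm$ground_truth$situation, "FEEDING_ALERT")
  run <- run_stream(engine_events(care_events = gm$care_events))
  raised <- run$alerts[run$alerts$phase == "RAISED", ]
  expect_equal(nrow(raised), 1)
  expect_equal(raised$situation, "FEEDING_ALERT")

  gmed <- generate_care_events(default_plan(), 1,
                               missed = data.frame(day = 1,
                                                   category = "medication"),
                               seed = 9, patient_id = "p1")
  run <- run_stream(engine_events(care_events = gmed$care_events))
  raised <- run$alerts[run$alerts$phase == "RAISED", ]
  expect_equal(raised$situation, "UNCHARACTERISTIC_MEDICATION")

  expect_error(generate_care_events(
    treatment_plan(feeding = c(0, 540)), 1,
    missed = data.frame(day = 1, category = "feeding"), seed = 1),
    "required_per_day = 0")
})

test_that("the benchmark scenario injects the documented per-patient counts", {
  scen <- build_table2_scenario(seed = 3)
  phys <- purrr::map_dbl(scen$patients, ~ nrow(.x$ground_truth$episodes))
  treat <- purrr::map_dbl(scen$patients, ~ nrow(.x$ground_truth$misses))
  expect_equal(phys, c(3, 7, 7, 5, 3))
  expect_equal(treat, c(4, 2, 7, 8, 2))
  expect_equal(unname(scenario_truth_totals(scen)), c(25, 23))

  # every situation axis occurs somewhere in the scenario
  kinds <- unlist(purrr::map(scen$patients, ~ .x$ground_truth$episodes$kind))
  axes <- unique(purrr::map_chr(kinds, ~ carewatch:::EPISODE_KINDS[[.x]]$axis))
  expect_setequal(axes, c("heart", "cardio", "temp"))

  scen2 <- build_table2_scenario(seed = 3)
  expect_identical(scen$patients[[2]]$samples, scen2$patients[[2]]$samples)
  expect_identical(scen$patients[[2]]$care_events,
                   scen2$patients[[2]]$care_events)
})

test_that("the engine reproduces injected counts across benchmark seeds", {
  for (seed in c(11, 12, 13, 14, 15)) {
    scen <- build_table2_scenario(seed = seed)
    for (p in scen$patients) {
      run <- monitor_stream(p$samples, p$care_events)
      expect_equal(attr(run$counts, "physiological_total"),
                   nrow(p$ground_truth$episodes),
                   info = sprintf("seed %d %s phys", seed,
                                  p$profile$patient_id))
      expect_equal(attr(run$counts, "treatment_total"),
                   nrow(p$ground_truth$misses),
                   info = sprintf("seed %d %s treat", seed,
                                  p$profile$patient_id))
    }
  }
})

test_that("oracle counts match spec cases and the engine", {
  gs <- generate_stream(patient_profile("p1"), DAY1, DAY1 + 86400, seed = 6)
  none <- treatment_plan(measurement = c(0, 540), medication = c(0, 540),
                         hygiene = c(0, 540), feeding = c(0, 540))
  expect_equal(unname(oracle_count(gs$samples, NULL, plan = none)), c(0, 0))

  scen <- build_table2_scenario(seed = 4)
  p3 <- scen$patients[[3]]
  oc <- oracle_count(p3$samples, p3$care_events)
  expect_equal(unname(oc), c(7, 7))
  run <- monitor_stream(p3$samples, p3$care_events)
  expect_equal(attr(run$counts, "physiological_total"), unname(oc["physiological"]))
  expect_equal(attr(run$counts, "treatment_total"), unname(oc["treatment"]))
})
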