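# Shared fixtures: everything is generated in code at test time.

DAY1 <- as.numeric(as.POSIXct("2026-01-05 00:00:00", tz = "UTC"))

ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

nominal_sample <- function(t = "2026-01-05T08:00:00", patient = "p1", ...) {
  args <- list(patient_id = patient, t = t, heart_rate = 72, body_temp = 36.5,
               blood_pressure = 120, spo2 = 97, breath_rate = 16,
               ecg_amp = 1.0, ecg_rr_cv = 0.05)
  over <- list(...)
  args[names(over)] <- over
  do.call(physiological_sample, args)
}

# a small random scenario: one day, 5-minute sampling, up to three episodes
# on distinct hours (so same-axis overlap is impossible) and up to two
# missed care slots
random_scenario <- function(seed) {
  withr::local_seed(seed)
  profile <- patient_profile(paste0("r", seed), period_sec = 300)
  n_ep <- sample(0:3, 1)
  kinds <- sample(names(carewatch:::EPISODE_KINDS), n_ep)
  hours <- if (n_ep) sample(1:22, n_ep) else integer()
  episodes <- purrr::map2(kinds, hours, function(k, h) {
    episode_spec(k, DAY1 + h * 3600, duration_min = sample(10:30, 1))
  })
  n_miss <- sample(0:2, 1)
  missed <- if (n_miss) {
    data.frame(day = 1, category = sample(c("measurement", "medication",
                                            "hygiene", "feeding"), n_miss))
  } else NULL
  gs <- generate_stream(profile, DAY1, DAY1 + 86400, episodes = episodes,
                        seed = NULL)
  gc <- generate_care_events(profile$plan, 1, missed = missed, seed = NULL,
                             patient_id = profile$patient_id,
                             start = as.Date("2026-01-05"))
  list(samples = gs$samples, care_events = gc$care_events,
       truth = list(episodes = gs$ground_truth, misses = gc$ground_truth))
}

# canonical form of a (situation, raise, clear) interval set for comparison
interval_set <- function(iv) {
  iv <- iv[order(as.numeric(iv$raised_at), iv$situation), , drop = FALSE]
  data.frame(situation = iv$situation,
             raised_at = as.numeric(iv$raised_at),
             cleared_at = as.numeric(iv$cleared_at))
}

expect_same_intervals <- function(run, samples, care_events,
                                  tick_interval = 60,
                                  cfg = default_thresholds(),
                                  plan = default_plan()) {
  eng <- interval_set(alert_intervals(run))
  ora <- interval_set(oracle_intervals(samples, care_events, cfg = cfg,
                                       plan = plan,
                                       tick_interval = tick_interval))
  expect_equal(eng, ora, ignore_attr = TRUE)
}
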