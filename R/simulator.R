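#' Synthetic patient profile
#'
#' Baseline vital-sign distribution for the simulator: per-vital mean and
#' standard deviation, sampling period, and the patient's treatment plan.
#' Baseline noise is Gaussian, truncated to the alarm-free interior of the
#' threshold configuration, so an episode-free stream can never cross a
#' criterion; defaults describe a stable adult at rest.
#'
#' @param patient_id Patient identifier.
#' @param heart_rate,body_temp,blood_pressure,spo2,breath_rate,ecg_amp,ecg_rr_cv
#'   Length-2 numeric `c(mean, sd)` per vital.
#' @param period_sec Sampling period in seconds (default 60).
#' @param plan A [treatment_plan()].
#' @return An object of class `patient_profile`.
#' @examples
#' patient_profile("p1")
#' @export
patient_profile <- function(patient_id,
                            heart_rate = c(72, 4), body_temp = c(36.5, 0.2),
                            blood_pressure = c(118, 6), spo2 = c(97, 1),
                            breath_rate = c(16, 2), ecg_amp = c(1.0, 0.1),
                            ecg_rr_cv = c(0.05, 0.01),
                            period_sec = 60, plan = default_plan()) {
  baseline <- rbind(heart_rate, body_temp, blood_pressure, spo2,
                    breath_rate, ecg_amp, ecg_rr_cv)
  dimnames(baseline) <- list(VITAL_SLOTS, c("mean", "sd"))
  if (any(baseline[, "sd"] < 0)) abort("baseline sd must be >= 0")
  structure(list(patient_id = as.character(patient_id), baseline = baseline,
                 period_sec = period_sec, plan = plan),
            class = "patient_profile")
}

#' @export
print.patient_profile <- function(x, ...) {
  cat("<patient_profile>", x$patient_id, " (period", x$period_sec, "s)\n")
  for (f in VITAL_SLOTS) {
    cat(sprintf("  %-14s %g +/- %g\n", f, x$baseline[f, 1], x$baseline[f, 2]))
  }
  invisible(x)
}

# episode kinds: which vital they drive, in which direction, past which
# criterion, and which alarm situation they must produce
EPISODE_KINDS <- list(
  heart_high   = list(slot = "heart_rate",     dir = +1, crit = "hr_hi",      axis = "heart"),
  heart_low    = list(slot = "heart_rate",     dir = -1, crit = "hr_lo",      axis = "heart"),
  bp_high      = list(slot = "blood_pressure", dir = +1, crit = "bp_hi",      axis = "heart"),
  bp_low       = list(slot = "blood_pressure", dir = -1, crit = "bp_lo",      axis = "heart"),
  ecg_abnormal = list(slot = "ecg_rr_cv",      dir = +1, crit = "ecg_rr_cv_max", axis = "heart"),
  tachypnea    = list(slot = "breath_rate",    dir = +1, crit = "breath_hi",  axis = "cardio"),
  bradypnea    = list(slot = "breath_rate",    dir = -1, crit = "breath_lo",  axis = "cardio"),
  hypoxia      = list(slot = "spo2",           dir = -1, crit = "spo2_lo",    axis = "cardio"),
  fever        = list(slot = "body_temp",      dir = +1, crit = "temp_hi",    axis = "temp"),
  hypothermia  = list(slot = "body_temp",      dir = -1, crit = "temp_lo",    axis = "temp")
)

#' Episode specification
#'
#' One injected abnormal interval: the named vital is driven strictly past
#' its criterion for the episode's duration.  The default magnitude is 5%
#' of the crossed criterion, which guarantees a strict crossing despite
#' the truncation of baseline noise.
#'
#' @param kind One of `heart_high`, `heart_low`, `bp_high`, `bp_low`,
#'   `ecg_abnormal`, `tachypnea`, `bradypnea`, `hypoxia`, `fever`,
#'   `hypothermia`.
#' @param start Episode start time.
#' @param duration_min Duration in minutes (> 0).
#' @param magnitude How far past the criterion to drive the vital, in the
#'   vital's units; `NULL` = 5% of the criterion.
#' @return An object of class `episode_spec`.
#' @examples
#' episode_spec("hypoxia", "2026-01-01T09:00:00", 5)
#' @export
episode_spec <- function(kind, start, duration_min, magnitude = NULL) {
  if (!kind %in% names(EPISODE_KINDS)) {
    abort(paste0("unknown episode kind: ", kind))
  }
  if (duration_min <= 0) abort("duration_min must be > 0")
  if (!is.null(magnitude) && magnitude <= 0) abort("magnitude must be > 0")
  structure(list(kind = kind, start = cw_time(start),
                 duration_min = duration_min, magnitude = magnitude),
            class = "episode_spec")
}

episode_situation <- function(kind) {
  PHYS_SITUATIONS[[EPISODE_KINDS[[kind]]$axis]]
}

episode_magnitude <- function(ep, cfg) {
  ep$magnitude %||% (0.05 * abs(cfg[[EPISODE_KINDS[[ep$kind]]$crit]]))
}

# run code under a given seed without disturbing the caller's RNG stream;
# seed = NULL uses the ambient RNG (the scenario-level generator)
with_sim_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) set.seed(NULL)
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# alarm-free clamp bounds: strictly inside both the alarm-free and the
# recovery regions, with a per-vital margin so boundary samples can neither
# alarm nor block recovery
alarm_free_bounds <- function(cfg) {
  rbind(
    heart_rate     = c(cfg$hr_lo + 1,            cfg$hr_hi - 1),
    body_temp      = c(cfg$temp_lo + 0.1,        cfg$temp_hi - 0.1),
    blood_pressure = c(cfg$bp_lo + 1,            cfg$bp_hi - 1),
    spo2           = c(cfg$spo2_lo + 0.5,        100),
    breath_rate    = c(cfg$breath_lo + 0.5,      cfg$breath_hi - 0.5),
    ecg_amp        = c(cfg$ecg_amp_range[1] + 0.05, cfg$ecg_amp_range[2] - 0.05),
    ecg_rr_cv      = c(0,                        cfg$ecg_rr_cv_max - 0.005)
  )
}

#' Generate a synthetic vital-sign stream
#'
#' Samples every vital at the profile's period over `[start, end)`.
#' Outside episodes, values are Gaussian noise around the profile baseline
#' truncated (clamped) to the alarm-free interior of `cfg`, so false
#' alarms are structurally impossible.  Inside an episode, the targeted
#' vital is held past its criterion by the episode magnitude.  Identical
#' seeds give byte-identical streams.
#'
#' @param profile A [patient_profile()].
#' @param start,end Stream bounds (`start < end`); samples are taken at
#'   `start, start + period, ...` strictly before `end`.
#' @param episodes A list of [episode_spec()]s inside `[start, end]`;
#'   episodes on the same situation axis must not overlap.
#' @param seed Integer seed, or `NULL` to draw from the ambient RNG.
#' @param cfg A [threshold_config()].
#' @return A list with `samples` (a tibble of [physiological_sample()]
#'   rows) and `ground_truth` (a tibble of the injected episodes:
#'   `patient_id`, `kind`, `situation`, `start`, `duration_min`,
#'   `magnitude`).
#' @examples
#' gs <- generate_stream(patient_profile("p1"), "2026-01-01T00:00:00",
#'                       "2026-01-01T02:00:00", seed = 1)
#' nrow(gs$samples)
#' @export
generate_stream <- function(profile, start, end, episodes = list(),
                            seed = NULL, cfg = default_thresholds()) {
  t0 <- cw_time(start); t1 <- cw_time(end)
  if (!(t0 < t1)) abort("start must be strictly before end")
  if (inherits(episodes, "episode_spec")) episodes <- list(episodes)

  # same-axis overlap check
  if (length(episodes) > 1) {
    info <- map_dfr(episodes, function(ep) {
      tibble(axis = EPISODE_KINDS[[ep$kind]]$axis, s = ep$start,
             e = ep$start + ep$duration_min * 60)
    })
    for (ax in unique(info$axis)) {
      sub <- info[info$axis == ax, ]
      sub <- sub[order(sub$s), ]
      if (nrow(sub) > 1 && any(sub$s[-1] < sub$e[-nrow(sub)])) {
        abort(paste0("overlapping episodes on the same situation axis: ", ax))
      }
    }
  }
  for (ep in episodes) {
    if (ep$start < t0 || ep$start + ep$duration_min * 60 > t1) {
      abort("episodes must lie within [start, end]")
    }
  }

  times <- seq(t0, t1, by = profile$period_sec)
  times <- times[times < t1]
  n <- length(times)
  bounds <- alarm_free_bounds(cfg)

  M <- with_sim_seed(seed, {
    out <- matrix(NA_real_, nrow = n, ncol = 7, dimnames = list(NULL, VITAL_SLOTS))
    for (f in VITAL_SLOTS) {
      x <- stats::rnorm(n, profile$baseline[f, "mean"], profile$baseline[f, "sd"])
      out[, f] <- pmin(pmax(x, bounds[f, 1]), bounds[f, 2])
    }
    out
  })

  for (ep in episodes) {
    k <- EPISODE_KINDS[[ep$kind]]
    mag <- episode_magnitude(ep, cfg)
    crit <- cfg[[k$crit]]
    idx <- times >= ep$start & times < ep$start + ep$duration_min * 60
    M[idx, k$slot] <- crit + k$dir * mag
  }

  samples <- tibble(patient_id = profile$patient_id, t = cw_posix(times))
  for (f in VITAL_SLOTS) samples[[f]] <- unname(M[, f])

  truth <- if (length(episodes)) {
    map_dfr(episodes, function(ep) {
      tibble(patient_id = profile$patient_id, kind = ep$kind,
             situation = episode_situation(ep$kind),
             start = cw_posix(ep$start), duration_min = ep$duration_min,
             magnitude = episode_magnitude(ep, cfg))
    })
  } else {
    tibble(patient_id = character(), kind = character(),
           situation = character(), start = cw_posix(numeric()),
           duration_min = numeric(), magnitude = numeric())
  }

  list(samples = samples, ground_truth = truth)
}

#' Generate a compliant-or-missed care-event log
#'
#' For each day and category, schedules `required_per_day` care events at
#' evenly spaced times of day (`(k - 1/2) * 24h / n`; for the default
#' 3-per-day plan: 04:00, 12:00, 20:00) with a small uniform jitter, so
#' that on a compliant day no gap between consecutive occurrences --
#' including the overnight gap -- exceeds the plan interval.  A missed
#' `(day, category)` entry omits the *middle* occurrence of that day,
#' which makes the category's alert condition hold strictly within that
#' day and clear at the day's next occurrence.
#'
#' @param plan A [treatment_plan()].
#' @param days Number of days to generate.
#' @param missed `NULL`, or a data frame with columns `day` (1-based day
#'   number) and `category`.
#' @param seed Integer seed, or `NULL` for the ambient RNG.
#' @param patient_id Patient identifier for the generated events.
#' @param start First calendar day (`Date`).
#' @param jitter_min Half-width of the uniform time jitter, minutes.
#' @return A list with `care_events` (tibble of [care_event()] rows) and
#'   `ground_truth` (tibble of induced irregularities: `patient_id`,
#'   `day`, `category`, `situation`).
#' @examples
#' gc <- generate_care_events(default_plan(), 2,
#'                            missed = data.frame(day = 1, category = "medication"),
#'                            seed = 1)
#' gc$ground_truth
#' @export
generate_care_events <- function(plan, days, missed = NULL, seed = NULL,
                                 patient_id = "p1",
                                 start = as.Date("2026-01-05"),
                                 jitter_min = 10) {
  start_t <- as.numeric(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"))
  missed <- if (is.null(missed)) {
    tibble(day = integer(), category = character())
  } else as_tibble(missed)
  if (nrow(missed)) {
    bad <- setdiff(missed$category, CARE_CATEGORIES)
    if (length(bad)) abort(paste0("unknown care category: ", paste(bad, collapse = ", ")))
    none <- missed$category[plan$required[missed$category] == 0]
    if (length(none)) {
      abort(paste0("cannot miss a category with required_per_day = 0: ",
                   paste(unique(none), collapse = ", ")))
    }
    if (anyDuplicated(missed[c("day", "category")])) {
      abort("at most one missed entry per (day, category)")
    }
  }

  with_sim_seed(seed, {
    rows <- list()
    for (d in seq_len(days)) {
      for (cat_ in CARE_CATEGORIES) {
        nreq <- plan$required[[cat_]]
        if (nreq == 0) next
        slots <- (seq_len(nreq) - 0.5) * 86400 / nreq
        hit <- nrow(missed) && any(missed$day == d & missed$category == cat_)
        if (hit) slots <- slots[-ceiling((nreq + 1) / 2)]
        if (!length(slots)) next
        jit <- stats::runif(length(slots), -jitter_min * 60, jitter_min * 60)
        rows[[paste(d, cat_)]] <- tibble(
          patient_id = patient_id,
          t = cw_posix(round(start_t + (d - 1) * 86400 + slots + jit)),
          category = cat_)
      }
    }
    events <- bind_rows(rows)
    events <- events[order(cw_time(events$t), events$category), ]

    truth <- if (nrow(missed)) {
      tibble(patient_id = patient_id, day = start + missed$day - 1,
             category = missed$category,
             situation = unname(TREAT_SITUATIONS[missed$category]))
    } else {
      tibble(patient_id = character(), day = as.Date(character()),
             category = character(), situation = character())
    }
    list(care_events = events, ground_truth = truth)
  })
}

#' Built-in five-patient benchmark scenario
#'
#' Builds the package's reference detection experiment: five patients
#' monitored for seven days at one-minute sampling, with per-patient
#' injected physiological-episode counts (3, 7, 7, 5, 3) and treatment
#' irregularity counts (4, 2, 7, 8, 2) -- 25 abnormal physiological
#' situations and 23 treatment irregularities in total.  Episode kinds are
#' cycled across all ten kinds (so every situation axis occurs); episodes
#' are one per day (09:00, 15 minutes) and irregularities are realised as
#' one omitted scheduled care occurrence per affected `(day, category)`.
#'
#' @param seed Integer seed; a single scenario-level RNG drives all
#'   patients, so the same seed reproduces the scenario byte-for-byte.
#' @param start First calendar day.
#' @param cfg A [threshold_config()].
#' @return A list of class `table2_scenario` with elements `patients` (a
#'   list of five `list(profile, samples, care_events, episodes, ground_truth)`)
#'   and `seed`.  Each patient's `ground_truth` has `episodes` and
#'   `misses` tibbles.
#' @examples
#' scen <- build_table2_scenario(seed = 1)
#' nrow(scen$patients[[3]]$ground_truth$episodes)
#' @export
build_table2_scenario <- function(seed = 1, start = as.Date("2026-01-05"),
                                  cfg = default_thresholds()) {
  phys_counts <- c(3, 7, 7, 5, 3)
  treat_counts <- c(4, 2, 7, 8, 2)
  days <- 7
  kinds <- names(EPISODE_KINDS)
  start_t <- as.numeric(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"))

  with_sim_seed(seed, {
    patients <- lapply(1:5, function(p) {
      pid <- paste0("patient-", p)
      profile <- patient_profile(pid)

      nphys <- phys_counts[p]
      episodes <- lapply(seq_len(nphys), function(j) {
        episode_spec(kinds[(p - 1 + j - 1) %% length(kinds) + 1],
                     start_t + (j - 1) * 86400 + 9 * 3600,
                     duration_min = 15)
      })

      ntreat <- treat_counts[p]
      ks <- seq_len(ntreat) - 1
      missed <- tibble(day = (ks %% days) + 1,
                       category = CARE_CATEGORIES[(ks + p - 1) %% 4 + 1])

      gs <- generate_stream(profile, start_t, start_t + days * 86400,
                            episodes = episodes, seed = NULL, cfg = cfg)
      gc <- generate_care_events(profile$plan, days, missed = missed,
                                 seed = NULL, patient_id = pid, start = start)
      list(profile = profile, samples = gs$samples,
           care_events = gc$care_events, episodes = episodes,
           ground_truth = list(episodes = gs$ground_truth,
                               misses = gc$ground_truth))
    })
    structure(list(patients = patients, seed = seed, start = start),
              class = "table2_scenario")
  })
}

#' @export
print.table2_scenario <- function(x, ...) {
  cat("<table2_scenario> 5 patients, 7 days, seed", x$seed, "\n")
  for (p in x$patients) {
    cat(sprintf("  %-10s: %d episodes, %d missed-care days\n",
                p$profile$patient_id, nrow(p$ground_truth$episodes),
                nrow(p$ground_truth$misses)))
  }
  invisible(x)
}

#' Ground-truth totals of a scenario
#'
#' @param scenario A `table2_scenario`.
#' @return Named numeric: injected `physiological` and `treatment` counts.
#' @export
scenario_truth_totals <- function(scenario) {
  c(physiological = sum(map_dbl(scenario$patients,
                                ~ nrow(.x$ground_truth$episodes))),
    treatment = sum(map_dbl(scenario$patients,
                            ~ nrow(.x$ground_truth$misses))))
}
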