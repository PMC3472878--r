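#' Daily treatment plan
#'
#' Per-patient daily requirements for the four care categories: how many
#' times per day each procedure must be performed (`required_per_day`) and
#' the maximum tolerated interval between consecutive occurrences
#' (`interval_min`, minutes).  A category falls into an alert condition
#' when, on the current day, the performed count is still below the daily
#' requirement *and* the time since the last occurrence strictly exceeds
#' the interval.
#'
#' The default plan requires three occurrences per day of every category
#' (morning / midday / evening) with a 540-minute (9-hour) interval, which
#' tolerates an even 8-hour spacing including the overnight gap.
#'
#' @param measurement,medication,hygiene,feeding Length-2 numeric
#'   `c(required_per_day, interval_min)` for the category.
#' @return An object of class `treatment_plan`.
#' @examples
#' default_plan()
#' treatment_plan(medication = c(2, 720))
#' @export
treatment_plan <- function(measurement = c(3, 540), medication = c(3, 540),
                           hygiene = c(3, 540), feeding = c(3, 540)) {
  specs <- list(measurement = measurement, medication = medication,
                hygiene = hygiene, feeding = feeding)
  req <- vapply(specs, function(x) as.numeric(x[[1]]), numeric(1))
  int <- vapply(specs, function(x) as.numeric(x[[2]]), numeric(1))
  if (any(req < 0)) abort("required_per_day must be >= 0")
  if (any(int <= 0)) abort("interval_min must be > 0")
  structure(list(required = req, interval_min = int), class = "treatment_plan")
}

#' @rdname treatment_plan
#' @export
default_plan <- function() treatment_plan()

#' @export
print.treatment_plan <- function(x, ...) {
  cat("<treatment_plan>\n")
  for (cat_ in CARE_CATEGORIES) {
    cat(sprintf("  %-12s: %g / day, max interval %g min\n",
                cat_, x$required[[cat_]], x$interval_min[[cat_]]))
  }
  invisible(x)
}

#' @rdname treatment_plan
#' @param x An object to convert / print.
#' @param ... Unused.
#' @export
as_tibble.treatment_plan <- function(x, ...) {
  tibble(category = CARE_CATEGORIES,
         required_per_day = unname(x$required[CARE_CATEGORIES]),
         interval_min = unname(x$interval_min[CARE_CATEGORIES]))
}

#' Running treatment counters
#'
#' Per-patient running state for the four care categories: the number of
#' times each procedure has been performed on the current calendar day
#' (`count`), the timestamp of the most recent occurrence (`last`, which
#' deliberately survives midnight because intervals are plain durations),
#' and the calendar day the counts refer to.
#'
#' @param day The calendar day (`Date`) the counts refer to.
#' @param count Named numeric of per-category counts for that day.
#' @param last Named `POSIXct` of most recent occurrence times (`NA` when
#'   no occurrence has been observed yet).
#' @return An object of class `treatment_counters`.
#' @examples
#' treatment_counters(as.Date("2026-01-01"))
#' @export
treatment_counters <- function(day,
                               count = stats::setNames(rep(0, 4), CARE_CATEGORIES),
                               last = stats::setNames(cw_posix(rep(NA_real_, 4)),
                                                      CARE_CATEGORIES)) {
  day <- as.Date(day)
  count <- count[CARE_CATEGORIES]
  last <- last[CARE_CATEGORIES]
  if (any(is.na(count)) || any(count < 0)) abort("counts must be >= 0 for every category")
  structure(list(day = day, count = count, last = last),
            class = "treatment_counters")
}

#' @export
print.treatment_counters <- function(x, ...) {
  cat("<treatment_counters> day:", format(x$day), "\n")
  for (cat_ in CARE_CATEGORIES) {
    cat(sprintf("  %-12s: %g today, last %s\n", cat_, x$count[[cat_]],
                if (is.na(x$last[[cat_]])) "never" else
                  format(x$last[[cat_]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")))
  }
  invisible(x)
}

#' @rdname treatment_counters
#' @param x An object to convert.
#' @param ... Unused.
#' @export
as_tibble.treatment_counters <- function(x, ...) {
  tibble(category = CARE_CATEGORIES, day = x$day,
         count_today = unname(x$count[CARE_CATEGORIES]),
         last_time = unname(x$last[CARE_CATEGORIES]))
}

#' Record a performed care procedure
#'
#' Increments the daily count of the event's category and moves its
#' last-occurrence time forward.  If the event belongs to a later calendar
#' day than the counters, the daily counts are reset first (see
#' [reset_daily()]) and the event is then counted on the new day.
#'
#' @param counters A [treatment_counters()] object.
#' @param ev A one-row [care_event()] tibble (or list with `t`, `category`).
#' @return The updated `treatment_counters`.
#' @examples
#' ctr <- treatment_counters(as.Date("2026-01-01"))
#' record_care_event(ctr, care_event("p1", "2026-01-01T08:00:00", "medication"))
#' @export
record_care_event <- function(counters, ev) {
  cat_ <- as.character(ev$category[[1]])
  if (!cat_ %in% CARE_CATEGORIES) abort(paste0("unknown care category: ", cat_))
  t <- cw_time(ev$t[[1]])
  prev <- cw_time(counters$last[[cat_]])
  if (!is.na(prev) && t < prev) {
    abort(sprintf("care event at %s is earlier than the recorded last %s time %s",
                  format_timestamp(t), cat_, format_timestamp(prev)))
  }
  d <- as.Date(cw_posix(t))
  if (d > counters$day) counters <- reset_daily(counters, d)
  counters$count[[cat_]] <- counters$count[[cat_]] + 1
  counters$last[[cat_]] <- cw_posix(t)
  counters
}

#' Roll treatment counters over to a new calendar day
#'
#' Daily counts are defined per calendar day and reset to zero at local
#' midnight; last-occurrence times are preserved across the reset because
#' interval conditions are plain durations that may span days.  A jump of
#' several days is a single reset to the new date.
#'
#' @param counters A [treatment_counters()] object.
#' @param date The new calendar day (`Date`); must not precede the current one.
#' @return The updated `treatment_counters` (unchanged if `date` equals the
#'   current day).
#' @export
reset_daily <- function(counters, date) {
  date <- as.Date(date)
  if (date < counters$day) {
    abort(sprintf("cannot reset counters backwards: %s < %s",
                  format(date), format(counters$day)))
  }
  if (date > counters$day) {
    counters$count[] <- 0
    counters$day <- date
  }
  counters
}

#' Patient-facing reminder schedule
#'
#' A fixed daily schedule of patient reminders ("time to take your
#' medication"), distinct from the caregiver alerts raised by the
#' compliance rules.  Each entry recurs every day at its time of day.
#'
#' @param entries A data frame with columns `time` (`"HH:MM"` or
#'   `"HH:MM:SS"`), `category` (care category) and `message`.
#' @return An object of class `reminder_schedule` (a tibble).
#' @examples
#' sched <- reminder_schedule(data.frame(
#'   time = "08:00", category = "medication", message = "morning medication"))
#' @export
reminder_schedule <- function(entries) {
  entries <- as_tibble(entries)
  stopifnot(all(c("time", "category", "message") %in% names(entries)))
  secs <- time_of_day_seconds(entries$time)
  if (any(is.na(secs)) || any(secs < 0) || any(secs >= 86400)) {
    abort("schedule times must be HH:MM[:SS] within 00:00-24:00")
  }
  if (!all(entries$category %in% CARE_CATEGORIES)) {
    abort("schedule entries must use a valid care category")
  }
  out <- entries[order(secs), , drop = FALSE]
  out$tod_sec <- sort(secs)
  class(out) <- c("reminder_schedule", class(out))
  out
}

time_of_day_seconds <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- suppressWarnings(as.numeric(p))
    if (length(p) < 2 || length(p) > 3 || anyNA(p)) return(NA_real_)
    p[1] * 3600 + p[2] * 60 + if (length(p) == 3) p[3] else 0
  }, numeric(1))
}

#' Reminders falling due in a time window
#'
#' Returns every scheduled reminder whose daily occurrence time falls in
#' the half-open window `(t_prev, t_now]`, in time order.  Windows may span
#' midnight or several days; concatenating the results over a partition of
#' a day yields each schedule entry exactly once.
#'
#' @param sched A [reminder_schedule()].
#' @param t_prev,t_now Window bounds (`POSIXct`, ISO string, or numeric
#'   seconds); `t_prev < t_now` required.
#' @return A tibble with columns `t`, `category`, `message`.
#' @examples
#' sched <- reminder_schedule(data.frame(
#'   time = "08:00", category = "medication", message = "morning medication"))
#' due_reminders(sched, "2026-01-01T07:59:00", "2026-01-01T08:01:00")
#' @export
due_reminders <- function(sched, t_prev, t_now) {
  a <- cw_time(t_prev); b <- cw_time(t_now)
  if (!(a < b)) abort("t_prev must be strictly earlier than t_now")
  days <- seq(day_index(a), day_index(b))
  occ <- map_dfr(days, function(d) {
    tibble(t = d * 86400 + sched$tod_sec,
           category = sched$category, message = sched$message)
  })
  occ <- occ[occ$t > a & occ$t <= b, , drop = FALSE]
  occ <- occ[order(occ$t), , drop = FALSE]
  occ$t <- cw_posix(occ$t)
  occ
}
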