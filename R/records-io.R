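#' Patient record archive
#'
#' Container for one patient's stored monitoring records: the sample
#' stream, the care-event log, and metadata (creation time, schema
#' version).  Archives serialise to a small XML dialect: root
#' `<patientRecord version="1" patient="..." created="...">` with one
#' `<sample t="...">` element per sample (one child element per present
#' vital, ECG as a single `<ecg amp rrcv>` element) and one
#' `<careEvent t="..." category="..."/>` per care event.  Attribute order
#' is fixed, and numbers are written as full-precision decimal strings, so
#' writes are byte-stable and `read_archive(write_archive(a))` is an exact
#' round trip.
#'
#' @param patient_id Patient identifier.
#' @param samples A tibble of [physiological_sample()] rows, time-sorted.
#' @param care_events A tibble of [care_event()] rows, time-sorted.
#' @param created_at Creation timestamp.
#' @return An object of class `record_archive`.
#' @examples
#' a <- record_archive("p1", physiological_sample("p1", "2026-01-01T08:00:00",
#'                                                heart_rate = 72))
#' p <- tempfile(fileext = ".xml")
#' write_archive(a, p)
#' read_archive(p)$patient_id
#' @export
record_archive <- function(patient_id, samples = NULL, care_events = NULL,
                           created_at = "2026-01-01T00:00:00") {
  samples <- if (is.null(samples)) {
    physiological_sample(character(), numeric())[0, ]
  } else as_tibble(samples)
  care_events <- if (is.null(care_events)) {
    tibble(patient_id = character(), t = cw_posix(numeric()),
           category = character())
  } else as_tibble(care_events)
  check_sorted <- function(x, what) {
    tn <- cw_time(x$t)
    bad <- which(diff(tn) < 0)
    if (length(bad)) {
      abort(paste0("out-of-order ", what, " timestamps at indices: ",
                   paste(utils::head(bad + 1, 5), collapse = ", ")))
    }
  }
  check_sorted(samples, "sample")
  check_sorted(care_events, "care-event")
  structure(list(patient_id = as.character(patient_id),
                 samples = samples, care_events = care_events,
                 created_at = format_timestamp(cw_time(created_at)),
                 schema_version = "1"),
            class = "record_archive")
}

#' @export
print.record_archive <- function(x, ...) {
  cat("<record_archive>", x$patient_id, "-", nrow(x$samples), "samples,",
      nrow(x$care_events), "care events\n")
  invisible(x)
}

ARCHIVE_SCHEMA_VERSION <- "1"

# full-precision decimal string: shortest representation that reparses to
# the identical double
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  redo <- as.numeric(out) != x
  if (any(redo)) out[redo] <- sprintf("%.17g", x[redo])
  out
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

SAMPLE_ELEMENTS <- c(heart_rate = "heartRate", body_temp = "bodyTemp",
                     blood_pressure = "bloodPressure", spo2 = "spo2",
                     breath_rate = "breathRate")
SAMPLE_UNITS <- c(heartRate = "bpm", bodyTemp = "C", bloodPressure = "mmHg",
                  spo2 = "pct", breathRate = "perMin")

#' @param a A `record_archive`.
#' @param path Destination/source file path.
#' @rdname record_archive
#' @export
write_archive <- function(a, path) {
  if (!inherits(a, "record_archive")) abort("`a` must be a record_archive")
  s <- a$samples
  body <- character()
  if (nrow(s)) {
    parts <- matrix("", nrow = nrow(s), ncol = length(SAMPLE_ELEMENTS) + 1)
    for (j in seq_along(SAMPLE_ELEMENTS)) {
      f <- names(SAMPLE_ELEMENTS)[j]
      el <- SAMPLE_ELEMENTS[[j]]
      v <- s[[f]]
      ok <- !is.na(v)
      parts[ok, j] <- sprintf('    <%s unit="%s">%s</%s>', el,
                              SAMPLE_UNITS[[el]], fmt_num(v[ok]), el)
    }
    ecg_ok <- !is.na(s$ecg_amp) & !is.na(s$ecg_rr_cv)
    parts[ecg_ok, ncol(parts)] <- sprintf('    <ecg amp="%s" rrcv="%s"/>',
                                          fmt_num(s$ecg_amp[ecg_ok]),
                                          fmt_num(s$ecg_rr_cv[ecg_ok]))
    inner <- apply(parts, 1, function(r) paste(r[nzchar(r)], collapse = "\n"))
    body <- sprintf('  <sample t="%s">\n%s\n  </sample>',
                    format_timestamp(cw_time(s$t)), inner)
  }
  ce <- a$care_events
  if (nrow(ce)) {
    body <- c(body, sprintf('  <careEvent t="%s" category="%s"/>',
                            format_timestamp(cw_time(ce$t)), ce$category))
  }
  doc <- c('<?xml version="1.0" encoding="UTF-8"?>',
           sprintf('<patientRecord version="%s" patient="%s" created="%s">',
                   a$schema_version, xml_escape(a$patient_id), a$created_at),
           body,
           "</patientRecord>")
  writeLines(doc, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname record_archive
#' @param source Path of an archive file to read.
#' @export
read_archive <- function(source) {
  if (!file.exists(source)) abort(paste0("archive not found: ", source))
  doc <- xml2::read_xml(source)  # malformed XML fails here with location info
  root <- xml2::xml_name(doc)
  if (root != "patientRecord") {
    abort(paste0("not a patient record document (root <", root, ">)"))
  }
  ver <- xml2::xml_attr(doc, "version")
  if (is.na(ver)) abort("archive is missing the schema version attribute")
  if (ver != ARCHIVE_SCHEMA_VERSION) {
    abort(paste0("unknown archive schema version: ", ver))
  }
  pid <- xml2::xml_attr(doc, "patient")
  created <- xml2::xml_attr(doc, "created")

  snodes <- xml2::xml_find_all(doc, "./sample")
  if (length(snodes)) {
    samples <- tibble(
      patient_id = pid,
      t = parse_timestamp(xml2::xml_attr(snodes, "t"))
    )
    for (j in seq_along(SAMPLE_ELEMENTS)) {
      child <- xml2::xml_find_first(snodes, paste0("./", SAMPLE_ELEMENTS[[j]]))
      samples[[names(SAMPLE_ELEMENTS)[j]]] <- as.numeric(xml2::xml_text(child))
    }
    ecg <- xml2::xml_find_first(snodes, "./ecg")
    samples$ecg_amp <- as.numeric(xml2::xml_attr(ecg, "amp"))
    samples$ecg_rr_cv <- as.numeric(xml2::xml_attr(ecg, "rrcv"))
  } else {
    samples <- NULL
  }

  cnodes <- xml2::xml_find_all(doc, "./careEvent")
  care <- if (length(cnodes)) {
    cat_ <- xml2::xml_attr(cnodes, "category")
    bad <- setdiff(unique(cat_), CARE_CATEGORIES)
    if (length(bad)) {
      abort(paste0("archive contains unknown care categories: ",
                   paste(bad, collapse = ", ")))
    }
    tibble(patient_id = pid, t = parse_timestamp(xml2::xml_attr(cnodes, "t")),
           category = cat_)
  } else NULL

  record_archive(pid, samples, care,
                 created_at = if (is.na(created)) "2026-01-01T00:00:00" else created)
}

#' Append-only JSON-lines alert sink
#'
#' One alert event per line with fields `t`, `patient_id`, `situation`,
#' `phase`, `detail`; the streaming-friendly stand-in for a networked
#' alert transport.
#'
#' @param alerts An alert tibble (`carewatch_run$alerts` or [tidy()] of a
#'   run).
#' @param path Destination file.
#' @param append Append to an existing log instead of overwriting.
#' @return `read_alert_log()` returns the alert tibble (with `detail` as a
#'   list-column).
#' @export
write_alert_log <- function(alerts, path, append = FALSE) {
  if (inherits(alerts, "carewatch_run")) alerts <- alerts$alerts
  lines <- vapply(seq_len(nrow(alerts)), function(i) {
    jsonlite::toJSON(list(
      t = format_timestamp(cw_time(alerts$t[i])),
      patient_id = alerts$patient_id[i],
      situation = alerts$situation[i],
      phase = alerts$phase[i],
      detail = alerts$detail[[i]]
    ), auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_alert_log
#' @export
read_alert_log <- function(path) {
  if (!file.exists(path)) abort(paste0("alert log not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble(t = cw_posix(numeric()), patient_id = character(),
                  situation = character(), phase = character(),
                  detail = list()))
  }
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
  tibble(
    t = parse_timestamp(map_chr(recs, "t")),
    patient_id = map_chr(recs, "patient_id"),
    situation = map_chr(recs, "situation"),
    phase = map_chr(recs, "phase"),
    detail = map(recs, "detail")
  )
}

#' Render a plain-text monitoring report
#'
#' Deterministic human-readable summary of an archive and (optionally) an
#' alert log: per-day minimum/mean/maximum of every reported vital,
#' per-day care-event counts against the plan, and the chronological alert
#' list.
#'
#' @param a A [record_archive()].
#' @param log Optional alert tibble or `carewatch_run`.
#' @param plan Optional [treatment_plan()] for the care-count comparison.
#' @return A single character string (embedded newlines).
#' @export
render_report <- function(a, log = NULL, plan = NULL) {
  out <- c(sprintf("Patient record report: %s", a$patient_id),
           sprintf("Samples: %d  Care events: %d", nrow(a$samples),
                   nrow(a$care_events)),
           "")

  if (nrow(a$samples)) {
    s <- a$samples
    s$day <- as.Date(s$t)
    out <- c(out, "Daily vital summary (min / mean / max):")
    for (d in sort(unique(s$day))) {
      sub <- s[s$day == d, , drop = FALSE]
      out <- c(out, sprintf("  %s", format(as.Date(d, origin = "1970-01-01"))))
      for (f in VITAL_SLOTS) {
        v <- sub[[f]][!is.na(sub[[f]])]
        if (!length(v)) next
        out <- c(out, sprintf("    %-14s %10.3f / %10.3f / %10.3f",
                              f, min(v), mean(v), max(v)))
      }
    }
    out <- c(out, "")
  }

  if (nrow(a$care_events)) {
    ce <- a$care_events
    ce$day <- as.Date(ce$t)
    out <- c(out, "Care events per day (performed / required):")
    req <- if (is.null(plan)) NULL else plan$required
    for (d in sort(unique(ce$day))) {
      sub <- ce[ce$day == d, , drop = FALSE]
      cnts <- vapply(CARE_CATEGORIES, function(cc) sum(sub$category == cc),
                     numeric(1))
      line <- paste(vapply(CARE_CATEGORIES, function(cc) {
        if (is.null(req)) sprintf("%s %d", cc, cnts[[cc]])
        else sprintf("%s %d/%g", cc, cnts[[cc]], req[[cc]])
      }, character(1)), collapse = "  ")
      out <- c(out, sprintf("  %s  %s", format(as.Date(d, origin = "1970-01-01")),
                            line))
    }
    out <- c(out, "")
  }

  if (!is.null(log)) {
    alerts <- if (inherits(log, "carewatch_run")) log$alerts else as_tibble(log)
    out <- c(out, sprintf("Alerts (%d):", nrow(alerts)))
    if (nrow(alerts)) {
      out <- c(out, sprintf("  %s  %-8s %s",
                            format_timestamp(cw_time(alerts$t)),
                            alerts$phase, alerts$situation))
    } else {
      out <- c(out, "  (none)")
    }
    rep_ <- situation_report(alerts)
    out <- c(out, "",
             sprintf("Physiological alarms raised: %d",
                     attr(rep_, "physiological_total")),
             sprintf("Treatment alerts raised    : %d",
                     attr(rep_, "treatment_total")))
  }
  paste(out, collapse = "\n")
}
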