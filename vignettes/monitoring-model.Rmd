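---
title: "The carewatch monitoring model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The carewatch monitoring model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carewatch)
```

## The monitoring problem

A home-care patient produces two streams: periodic multi-sensor vital
signs (heart rate, body temperature, systolic blood pressure, SpO₂,
breath rate, summary ECG features) and sparse care events recording that
a measurement round, medication intake, hygiene procedure, or feeding was
actually performed.  The engine's job is to raise a caregiver alarm when
a vital strictly crosses its criterion, to raise a compliance alert when
a care category falls behind its daily plan, and to clear each situation
again through an explicit recovery condition — not merely the absence of
the alarm condition.

## The three-level rule cycle

Every new event (sample, care event, or bare clock tick) triggers one
reasoning cycle on a per-patient blackboard with separate domain data
(latest value per sensor, treatment counters, plan) and control data
(phase, active situations, rule-firing trace).

1. **Treatment determination** runs first, but only while *no
   physiological alarm is active*.  For each category the alert rule
   compares the day's count with the daily requirement and the elapsed
   time since the last occurrence with the planned interval (both
   strict); for a category whose alert is already active, the recovery
   rule fires as soon as that condition no longer holds.
2. **Physiological reasoning** then evaluates the three axes in the
   fixed order heart → cardiorespiratory → body temperature, using the
   latest reported value of each sensor.  A quiet axis is tested with its
   alarm rule, an active axis only with its recovery rule.

Rule outcomes are order-independent; the fixed order only makes the
control trace reproducible.  Because the gate is checked at the start of
the cycle, a cycle that clears the last physiological alarm does *not*
evaluate treatment rules itself — a deferred treatment alert fires on the
first cycle after clearing (for streaming input, at most one tick
interval later).  This also means a treatment alert raised in the same
cycle as a new physiological alarm is legitimate: the gate was open when
the treatment phase ran.

Several physiological alarms may be active simultaneously; the axes are
independent.  `NORMAL` is implied exactly when no physiological alarm is
active.

## Hysteresis and boundary semantics

All comparisons are strict, exactly as the criteria are written
(`H > 100`, `H < 60`, recovery `60 < H < 100`).  A value equal to a
criterion therefore changes no state in either direction; this is the
neutral gap of the hysteresis pair.  Recovery rules are conservative:
they require *every* clause value to be present and strictly inside its
reference interval, so an alarm is never cleared on absent evidence,
while an alarm clause with a missing value is simply skipped.  The test
suite checks these properties against an independently coded truth table
over grids spanning each threshold, and the engine as a whole against a
brute-force oracle that re-derives all raise/clear intervals from
scratch.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `hr_lo`, `hr_hi` | 60, 100 | beats/min | heart-rate criteria |
| `bp_lo`, `bp_hi` | 90, 160 | mmHg | systolic blood-pressure criteria |
| `breath_lo`, `breath_hi` | 8, 24 | breaths/min | breath-rate criteria |
| `spo2_lo` | 90 | % | SpO₂ lower criterion |
| `temp_lo`, `temp_hi` | 35, 37 | °C | body-temperature criteria |
| `ecg_amp_range` | [0.5, 2.5] | mV | normal ECG peak-amplitude range |
| `ecg_rr_cv_max` | 0.15 | — | max normal RR-interval CV |
| `required_per_day` | 3 per category | count | daily care requirement |
| `interval_min` | 540 | min | max tolerated gap between occurrences |
| `tick_interval` | 60 | s | engine clock when no data arrives |

Design choices behind the less obvious ones:

* **Blood pressure is systolic.**  A single pressure value with 90/160
  criteria matches systolic ranges; the interpretation is configurable
  through the thresholds, and nothing else in the engine depends on it.
* **The ECG feature pair** concretises "abnormal magnitudes and cyclic
  patterns" as peak amplitude (magnitude) and the coefficient of
  variation of RR intervals (cyclic regularity).  The normal ranges are
  package defaults, and the whole predicate is pluggable
  (`ecg_predicate` argument of `run_stream()`), since summary ECG
  abnormality has no single canonical definition.
* **The default plan (3/day, 540 min)** makes a compliant day exactly
  feasible: three occurrences at 04:00/12:00/20:00 leave 8-hour gaps,
  including overnight, all strictly below the 9-hour interval.
* **Cold start:** with no occurrence on record, elapsed time is measured
  from local midnight of the current day, so a fully missed morning
  routine still alerts the same day.
* **Day boundary:** daily counts reset at local midnight (the first
  event of a new day); last-occurrence times survive the reset because
  intervals are plain durations that may span days.
* **Tick interval 60 s:** elapsed-time conditions must be able to fire
  without fresh sensor data, so the stream driver inserts bare ticks
  between data events; nothing in the rules depends on the tick spacing
  beyond alert-latency granularity.
* **Timestamps** are timezone-naive local time at second resolution,
  held internally as UTC epoch seconds so calendar days are exact
  86400-second blocks.
* **Clearing is immediate:** a recovery rule fires on the first
  conforming evaluation; no persistence duration is required before an
  alarm is suspended.
* **Physiological reasoning is never blocked** by measurement
  irregularity: a fresh sample is always evaluated, and an irregular
  measurement schedule is reported through its own alert instead.
* **Reminders** (the patient-facing daily schedule) are emitted as
  `REMINDER` events distinct from caregiver alerts, and acknowledging a
  reminder does not create a care event — only explicit care events
  move counters.

## The simulator

The simulator emulates the *conditions* a detection experiment needs,
not physiology:

* **Baselines** (HR 72±4, T 36.5±0.2 °C, BP 118±6 mmHg, SpO₂ 97±1 %,
  breath 16±2 /min, ECG 1.0±0.1 mV and CV 0.05±0.01) are Gaussian noise
  truncated to the alarm-free interior of the thresholds, with a small
  per-vital margin that also keeps values strictly inside the recovery
  intervals.  False positives are therefore structurally impossible on
  episode-free streams — the reference experiment reports none, and no
  noise model for false alarms is available to emulate.
* **Episodes** hold one vital past its criterion by a magnitude
  defaulting to 5% of the criterion, which guarantees a strict crossing;
  recovery is guaranteed by the truncation above.
* **Care events** are scheduled at evenly spaced times of day with ±10
  minutes of uniform jitter; an injected irregularity omits the *middle*
  occurrence of its day, so the alert condition holds strictly within
  that day (raise after the interval elapses, clear at the day's next
  occurrence) and adjacent-day irregularities cannot merge into one
  alert interval.
* **The benchmark scenario** monitors five patients for seven days at
  one-minute sampling with per-patient episode counts (3, 7, 7, 5, 3)
  and irregularity counts (4, 2, 7, 8, 2), episodes cycled over all ten
  kinds so every situation axis occurs.  One scenario-level RNG drives
  everything, so one seed reproduces the scenario byte-for-byte.

What the simulator does *not* model — sensor dropout, drift, motion
artefacts, values that hover at a criterion, overlapping same-axis
pathology — bounds what passing tests show: they demonstrate that the
rule engine implements its stated semantics exactly, not that those
thresholds are clinically sufficient on noisy real devices.

## Numerical and degenerate-input choices

* Numbers in XML archives are written as shortest decimal strings that
  reparse to the identical double (15 significant digits, extended to 17
  where needed); configuration files use the same encoding.  Attribute
  order is fixed, so writes are byte-stable.
* An out-of-order event, an unknown care category, or an unknown patient
  is an error; a malformed sample value is a reported validation
  violation, not an exception.
* Empty streams, empty archives, and categories with
  `required_per_day = 0` are all valid degenerate inputs (a zero
  requirement can never alert and cannot be "missed" in a scenario).
* Re-alert reminders for persisting situations exist but default to off;
  a situation otherwise emits exactly one `RAISED` per entry.

## Problem sizes used by the test suite

The suite checks engine/oracle interval equivalence on 100 random
one-day scenarios (5-minute sampling, up to three episodes and two
missed care slots each), zero false positives on 50 episode-free
compliant days, adversarial gating interleavings where episodes cover
the instants treatment alerts would fire, exact XML round trips
including a 10,080-sample week-long archive, and the full five-patient
benchmark across several seeds.  `scripts/acceptance.R` runs the
benchmark end to end (≈50,400 samples) and reports detection accuracy
and the two raise totals; all three are computed at run time from the
simulated archives and the engine's alert log.

## Known limitations

* Single-sample rule conditions only: no trends, derivatives, or
  multi-sample smoothing, so a one-sample glitch past a criterion raises
  a (correct, per the rules) alarm.
* The ECG abstraction is feature-level; no waveform processing.
* Alert delivery is a JSON-lines sink; no transport, acknowledgement, or
  escalation semantics.
* Calendar handling assumes timezone-naive local time; daylight-saving
  transitions are outside the model.
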