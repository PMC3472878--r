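# carewatch

Rule-based monitoring of vital signs and home-care compliance.

`carewatch` is an R implementation of a knowledge-based home-care
monitoring engine for caregivers and clinical-decision-support developers.
It watches two kinds of streams for a recovering or chronically ill
patient at home:

* **physiological samples** — heart rate *H(t)* (beats/min), body
  temperature *T(t)* (°C), systolic blood pressure *P(t)* (mmHg), blood
  oxygen saturation *O(t)* (%), breath rate *B(t)* (breaths/min), and a
  summary ECG feature pair *C(t)* (peak amplitude, RR-interval
  coefficient of variation);
* **care events** — timestamped records that a physiological measurement
  round, medication intake, hygiene procedure, or feeding was performed.

## The rule model

Reasoning is organised in three levels on a blackboard store with strict
domain/control partitions:

* a **strategy rule** triggers a reasoning cycle whenever a new sample,
  care event, or clock tick arrives;
* **control rules** pick the phase: *treatment determination* runs first,
  but only while no physiological alarm is active; *physiological
  reasoning* then evaluates the vital-sign axes in the fixed order heart →
  cardiorespiratory → body temperature;
* **knowledge rules** raise and clear seven situations with hysteresis.

The physiological alarm rules fire on a strict threshold crossing, e.g.
for the heart axis

```
alarm:    H(t) > 100  or  H(t) < 60   (or P(t) ∉ (90, 160), or abnormal ECG)
recover:  60 < H(t) < 100  and  90 < P(t) < 160  and  normal ECG
```

so a value sitting exactly on a criterion fires neither rule, and an
alarm is cleared only by the distinct recovery rule (never by missing
data).  The treatment alert rules compare, per care category *c*, the
day's performed count against the daily requirement and the elapsed time
since the last occurrence against the planned interval:

```
alert(c):  count_today(c) < required_per_day(c)  and  t − last_time(c) > interval(c)
```

with the matching recovery rule firing as soon as that condition no
longer holds.  The eight situations are `NORMAL` plus three alarms
(`ABNORMAL_HEART`, `ABNORMAL_CARDIORESPIRATORY`,
`ABNORMAL_BODY_TEMPERATURE`) and four alerts (`IRREGULAR_MEASUREMENT`,
`UNCHARACTERISTIC_MEDICATION`, `HYGIENE_ALERT`, `FEEDING_ALERT`).

The package also provides a seeded synthetic patient simulator (baseline
vitals with truncated Gaussian noise, injected threshold-crossing
episodes, missed-care irregularities, ground-truth sidecars), an
independent brute-force detection oracle used to cross-check the engine,
XML record archives, a JSON-lines alert sink, plain-text reports,
ggplot2 plots (`autoplot()`, `plot_vitals()`), and a command-line front
end (`inst/cli/carewatch.R`).

## Worked example

```r
library(carewatch)

gs <- generate_stream(
  patient_profile("p1"),
  "2026-01-05T00:00:00", "2026-01-05T06:00:00",
  episodes = episode_spec("hypoxia", "2026-01-05T02:00:00", 10),
  seed = 1)

run <- monitor_stream(gs$samples)
run
#> <carewatch_run> 1 patient(s), 360 events
#>   alerts: 2 ( 1 RAISED, 1 CLEARED )
#>   physiological alarms raised: 1
#>   treatment alerts raised    : 0

tidy(run)
#> # A tibble: 2 × 5
#>   t                   patient_id situation                  phase   detail
#>   <dttm>              <chr>      <chr>                      <chr>   <list>
#> 1 2026-01-05 02:00:00 p1         ABNORMAL_CARDIORESPIRATORY RAISED  <named list>
#> 2 2026-01-05 02:10:00 p1         ABNORMAL_CARDIORESPIRATORY CLEARED <named list>

run$alerts$detail[[1]]
#> $breath_rate
#> [1] 16.47532
#>
#> $spo2
#> [1] 85.5
#>
#> $video_ref
#> [1] "video://p1"
```

The simulator drove SpO₂ to 85.5% (5% past the 90% criterion) for ten
minutes starting at 02:00; the engine raised the cardiorespiratory alarm
at the first crossing sample, attached the triggering breath-rate and
saturation values, and cleared it at the first sample back above 90%.
`glance(run)` gives the one-row run summary; `autoplot(run)` draws the
alert timeline and `plot_vitals(gs$samples)` the vitals against their
criteria.

From a shell, the same pipeline is:

```sh
Rscript inst/cli/carewatch.R simulate --table2 --seed 1 --out sim/
Rscript inst/cli/carewatch.R monitor sim/patient-*.xml \
    --alerts sim/alerts.jsonl --ground-truth sim/ground_truth.json
Rscript inst/cli/carewatch.R report sim/patient-1.xml --alerts sim/alerts.jsonl
```

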