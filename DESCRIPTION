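Package: carewatch
Title: Rule-Based Monitoring of Vital Signs and Home-Care Compliance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A knowledge-based monitoring engine for home-care patients.
    Streams of timestamped vital-sign samples (heart rate, body temperature,
    systolic blood pressure, blood oxygen saturation, breath rate, summary
    ECG features) and care events (physiological measurement, medication,
    hygiene, feeding) are evaluated by a three-level rule system: strategy
    and control rules schedule two reasoning phases on a blackboard store,
    and knowledge rules with hysteresis raise and clear three physiological
    alarm situations and four treatment alert situations. Includes a seeded
    synthetic patient simulator with injected threshold-crossing episodes
    and missed-care irregularities, an independent brute-force detection
    oracle, XML record archives, a JSON-lines alert sink, plain-text
    reports, ggplot2 visualisations, and command-line entry points for
    simulation, monitoring, and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
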