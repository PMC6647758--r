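Package: fullflow
Title: Diabetes Self-Collected Health Data Analytics and Reporting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytic engine for consultation dashboards built on patient
    self-collected diabetes data. Reads FHIR R4 JSON bundles of Observation,
    Goal and MedicationStatement resources into a typed dataset; computes
    summary tables (counts, daily averages, means, pooled standard
    deviation), estimated hemoglobin A1c with gating rules and NGSP/IFCC
    conversion, time-in-range partitions, rule-of-thumb insulin ratios
    (100/85 and 400 rules), insulin-on-board and carbohydrates-on-board
    kinetics, moving-average daily distributions, per-day aggregation views,
    knowledge-based data-reliability grading, noticeable-event detection
    with causes, goal progress, and four-state color grading; assembles
    everything into a deterministic six-section report document. Includes a
    seeded scenario generator producing realistic synthetic patient
    datasets so the whole pipeline is testable without real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
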