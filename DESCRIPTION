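Package: adlmonitor
Title: Long-Term Behavior-Change Detection from Activity-Labeled Smart-Home Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ambient-assisted-living behavior monitoring of elderly
    people. Reads activity-labeled smart-home sensor logs, learns a personal
    normal behavior pattern by density-based clustering of activity start
    times and durations (DBSCAN with noise removal), scores each observed day
    against the learned routine with temporal-intersection similarity and
    duration scores, detects deviation periods and per-day point anomalies
    (missing activities, abnormal durations, abnormal toileting frequency),
    and assesses a suspected-disease level with a Mamdani fuzzy inference
    system (trapezoidal membership, MIN/MAX rule evaluation, centroid
    defuzzification). Includes a seeded synthetic-log generator with
    injectable anomaly scenarios and day-level sensitivity/accuracy
    evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
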