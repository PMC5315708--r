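Package: scopemetrics
Title: Endoscope-Control Performance Metrics for Robot-Assisted Surgery Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes objective endoscope-control ("camera") performance metrics
    from time-stamped robot-assisted surgery trial telemetry: camera movement
    frequency, duration, and interval, alongside conventional efficiency metrics
    (completion time, economy of motion, master workspace range). Segments camera
    movement episodes from system events or, as a fallback, from endoscope
    kinematics. Includes a seeded synthetic surgeon-cohort simulator built on an
    alternating renewal process, and a construct-validity analysis layer:
    per-exercise group comparisons with Student's t tests, min-max normalized
    group discrimination with pairwise metric comparisons, and Pearson
    correlations of camera metrics against efficiency targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
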