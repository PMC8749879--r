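Package: rebound
Title: Athlete Fatigue and Recovery Monitoring from Wearable-Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for monitoring fatigue and performance recovery in team-sport
    athletes from wearable-sensor recordings. Extracts ballistic jump parameters
    (flight-time jump height, mean exerted power, reactive strength index and
    spring-mass leg stiffness) from foot-mounted accelerometer traces of repeated
    vertical-jump (Bosco) trials, computes session-level physiological metrics
    (mean heart rate, GNSS covered distance, Wingate mean and peak power), and
    runs a small-sample nonparametric analysis battery (exact Wilcoxon
    signed-rank by enumeration, Friedman test with Bonferroni post hoc, Cliff's
    delta, coefficient of quartile variation) over a multi-week study design.
    Includes a physically grounded synthetic-cohort generator with exact ground
    truth for end-to-end validation, CSV readers and writers for all trace
    formats, and a report pipeline producing weekly pre/post comparison tables,
    temporal-trend tests and downfall/recovery phase detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    geosphere,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr
Config/testthat/edition: 3
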