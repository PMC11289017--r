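Package: gazebench
Title: Benchmarking Dual Eye-Tracker Recordings with a Standardized Test Battery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing two eye trackers that record the same viewer
    simultaneously, e.g. a high-rate laboratory tracker against a 30 Hz
    webcam-based system. Provides screen-geometry conversions between pixels
    and visual angle, generators for a five-task test battery (fixation grid,
    Brownian-motion smooth pursuit, free viewing, head roll and head yaw), a
    parametric dual-tracker gaze simulator, clock-lag estimation by time-lag
    cross-correlation with resampling onto a common timebase, a dispersion-based
    (I-DT family) fixation detector, data-quality metrics (accuracy, two
    precision measures including RMS-S2S, data loss, per-axis gaze correlations,
    drift correction), and the statistical summary stage (Type-II factorial
    ANOVA, paired t tests, calibration summaries, Gaussian-kernel gaze
    heatmaps, and a battery-wide report).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
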