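Package: accomstep
Title: Accommodative Step-Response Dynamics Under Maddox Cue Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quality control, preprocessing and analysis of 50 Hz
    photorefraction recordings of accommodative step responses. Reads
    two-eye refraction traces with stimulus event logs, applies file-level
    artifact rejection and eye-substitution repair, zero-phase Butterworth
    filtering, baseline alignment and movement segmentation, then extracts
    per-movement peak velocity (the preprogrammed response component) and
    final amplitude (the feedback component) for each Maddox cue condition
    (blur, disparity, proximal, alone and in combination). Group inference
    uses Kruskal-Wallis one-way ANOVA with tie correction and
    Dwass-Steel-Critchlow-Fligner all-pairs comparisons, with Levene and
    Shapiro-Wilk assumption checks and two-level (2-SD intra-participant,
    1.5xIQR inter-participant) outlier handling. A synthetic-cohort
    generator with per-cue response gains, measurement noise and
    blink/dropout artifacts makes every stage testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tibble,
    utils
Suggests:
    car,
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
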