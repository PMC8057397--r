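Package: wearbio
Title: Digital Biomarkers from Wearable Heart-Rate, Step and Glucose Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Device-agnostic toolkit that turns long-format wearable time
    series (heart rate, step counts, interstitial glucose) into digital
    biomarkers. Provides validated ingestion and uniform resampling of
    timestamped channels, per-day and per-hour data-completeness summaries,
    resting-heart-rate estimation by penalized search over low-activity
    subsets, sleep-episode detection from heart rate and actigraphy via
    heuristic labeling and cross-validated classifiers, a 28-metric glycemic
    variability report for continuous glucose monitor traces (including MAGE,
    MODD, CONGA, LBGI/HBGI, ADRR, GMI and time-in-range), LOWESS trend
    smoothing, ground-truth-bearing synthetic signal generators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    glmnet,
    e1071
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
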