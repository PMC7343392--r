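Package: lcarousal
Title: Arousal-Related Memory, Autonomic Tone and Brainstem-BOLD Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-modal studies of arousal-related
    memory processing: signal-detection-theory scoring of emotional
    recognition/recollection with likelihood-ratio bias correction,
    pulse-oximeter beat cleaning and heart-rate-variability measures
    (rMSSD), salivary alpha-amylase stage deltas, Welch cross-spectral
    magnitude-squared coherence and phase-lag estimation between ROI BOLD
    and HRV series with AR(1)-matched surrogate null distributions and
    partial coherence, and stage-wise association statistics
    (repeated-measures correlation with bootstrap CIs, random-intercept
    mixed models, Johnson-Neyman regions of significance, Tukey contrasts,
    FDR). Includes a synthetic-data generator with known ground truth so
    the full chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
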