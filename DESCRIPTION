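Package: pupilpop
Title: Trial-Level Analysis of Pupil-Linked Arousal and Visual Orienting in Infant Eye-Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for infant audiovisual pop-out experiments combining
    pupillometry and gaze analysis. Builds counterbalanced paired-trial
    experiment schedules, simulates 600 Hz binocular eye-tracking sessions
    with known injected effects, preprocesses gaze (gap interpolation,
    binocular averaging, area-of-interest coding, first-entry latency) and
    pupil signals (moving-average smoothing, dynamic-offset binocular mean,
    validity recoding, baseline/response windows, phasic dilation), applies
    trial rejection criteria and participant inclusion rules, performs
    tree-based multiple imputation with Rubin pooling, and fits
    random-intercept linear and binomial mixed models with single-term
    likelihood-ratio tests, quadratic-trend tests, and marginal contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    lme4,
    rpart,
    stats,
    utils
Suggests:
    emmeans,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
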