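Package: whiskerkin
Title: Whisker Kinematics Quantification and Mixed-Model Inference for
    Rodent Exploration Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies rodent whisking behaviour from tracker-style
    per-frame whisker-angle tables: per-clip kinematic metrics (mean angular
    position, amplitude, asymmetry, spread, protraction and retraction
    speeds, locomotion speed), clip quality control, pre-contact/during-
    contact segmentation for object-exploration clips, nose-to-object
    distance and arena zone occupancy. Provides the matching inference
    layer (random-intercept linear mixed models with Kenward-Roger F-tests,
    MANOVA with partial eta-squared effect-size bands, Tukey post hoc
    contrasts, Pearson chi-squared tests on zone timings) and a synthetic
    whisking-cohort generator so the whole pipeline is testable without
    high-speed video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    emmeans,
    jsonlite,
    lme4,
    lmerTest,
    pbkrtest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
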