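Package: bruxscore
Title: Heart-Rate-Coupled Sleep Bruxism Scoring from Portable EMG/ECG Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores sleep bruxism from overnight two-channel masseter
    electromyography plus single-lead electrocardiography, in the style of
    portable home screening devices. Implements maximum-voluntary-clench
    calibration and percent-MVC normalization, EMG burst detection with
    hysteresis, grouping and tonic/phasic/mixed classification of masticatory
    events, beat-domain heart-rate surge detection, surge-coupled episode
    scoring, the bruxism index with its greater-than-two-episodes-per-hour
    diagnostic cut-off, screening sensitivity/specificity, and the
    nonparametric cohort statistics (descriptives with coefficient of
    variation, tie-corrected Mann-Whitney z, Spearman rank correlation with
    t conversion, 2x2 chi-square). A synthetic-night generator plants tonic,
    phasic and mixed events with known cardiac coupling so the whole chain is
    testable against ground truth without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'bruxscore-package.R'
    'calibration.R'
    'cli.R'
    'cohort-stats.R'
    'diagnosis.R'
    'edf.R'
    'io.R'
    'preprocess.R'
    'scoring.R'
    'synthetic.R'
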