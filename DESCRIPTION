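Package: towvid
Title: Validation and Precision Modelling of Towed-Video Abundance Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for validating towed-video surveys of benthic organisms
    (developed around surveys of the European flat oyster, Ostrea edulis)
    and for planning monitoring programmes. Simulates hierarchical
    video-survey data with observer error and imperfect, status-dependent
    detection; scores live/dead classification success with
    confusion-matrix statistics (correct classification rate, sensitivity,
    specificity, Cohen's kappa); fits the nested mixed ANOVA of a
    site/transect/section/observer/reading design, derives expected mean
    squares by the Cornfield-Tukey algorithm, and estimates variance
    components by method-of-moments and REML; and propagates the variance
    components into predicted precision (standard error of mean abundance)
    for arbitrary survey designs, including per-square-metre conversion,
    standard-error-versus-area curves and a required-area solver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    readxl,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
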