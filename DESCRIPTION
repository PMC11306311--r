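Package: sleepmetab
Title: Crossover Sleep-Deprivation Metabolomics Pipeline with QC-Anchored
    Preprocessing and Time-Course Profile Classification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for untargeted oral-fluid metabolomics time-course
    studies with a crossover sleep-deprivation design. Implements
    QC-pool-anchored LOWESS run-order drift correction, four-criterion
    feature quality filtering (blank presence, QC relative standard
    deviation, dilution-series linearity, dispersion ratio) plus
    missingness filters, one-fifth limit-of-detection imputation, log10
    transformation and subject-wise z-score normalization,
    repeated-measures two-way analysis of variance with
    Greenhouse-Geisser correction and percent-of-total-variation
    decomposition, per-timepoint paired testing between conditions, and a
    rule-based classification of features into sleep-related (linear or
    rhythmic), non-adaptive, non-robust, or unaffected time-course
    profiles. Includes a synthetic-data generator emulating a 13-subject,
    2-condition, 7-timepoint crossover design with diurnal rhythms,
    dominant between-subject variance, multiplicative run-order drift,
    QC pools, process blanks, dilution series, and limit-of-detection
    censoring, so that every pipeline stage is testable against known
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
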