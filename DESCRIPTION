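Package: predcfa
Title: Prediction Configural Frequency Analysis for Categorical Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Person-oriented typal analysis of multiway categorical data by
    configural frequency analysis (CFA). Builds multiway contingency tables,
    computes expected cell frequencies under total independence, and performs
    per-cell chi-square CFA as well as prediction CFA, in which every
    predictor-configuration by criterion-category cell is collapsed to a
    fourfold table and tested with a one-sided Fisher exact test. Implements
    the two-stage split-half design (exploratory screening without alpha
    adjustment, confirmatory testing of the screened cells under Holm
    family-wise error control), survey categorization rules (sum scores,
    median and mean splits, majority-direction scoring, age banding), a
    synthetic cohort generator with planted configuration-criterion
    associations, and the printed p-value matrix of a published
    dialysis-patient application as a packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
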