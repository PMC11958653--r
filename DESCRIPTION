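Package: cogload
Title: Physiological and Behavioural Analysis of Work-Instruction Cognitive Load
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for assessing how the format of assembly work
    instructions affects operator cognitive load and operational efficiency.
    Implements preprocessing and feature extraction for wearable physiological
    recordings (heart-rate variability from photoplethysmography, tonic/phasic
    skin-conductance decomposition via continuous decomposition analysis,
    wrist accelerometry), NASA-TLX and short Dundee Stress State Questionnaire
    scoring, marker-based assembly-precision scoring, a sphericity-corrected
    repeated-measures statistical battery, and condition classification by
    backward-elimination logistic regression. Ships a synthetic-study generator
    with known ground truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    nnet,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    car,
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
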