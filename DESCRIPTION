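Package: crossmodal
Title: Single-Unit and Behavioral Analysis of Cross-Modal Responses in Gustatory Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for analysing extracellular single-unit
    responses to cross-modal (auditory, visual, somatosensory, olfactory)
    and gustatory stimuli, together with conditioned orofacial behavior.
    Implements change-point detection of stimulus-evoked firing-rate
    modulations from the cumulative spike-time distribution, taste
    selectivity by two-way ANOVA, auROC normalization of peristimulus
    histograms, a cue-similarity log-ratio index with a shuffled-pairing
    null band, pseudo-population nearest-template decoding with bootstrap
    confidence bands, a bootstrap test of response-convergence
    independence, frame-difference quantification of mouth movements with
    learning-day detection, and the proportion-comparison statistics
    (equality of proportions, Pearson chi-square, Marascuillo procedure,
    Student t). A seeded synthetic-data generator emulates the statistical
    structure of the recordings so that every stage is testable without
    raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
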