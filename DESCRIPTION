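Package: eegmicrostates
Title: Resting-State EEG Microstate Segmentation and Trait Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of multichannel resting-state EEG into quasi-stable
    topographic microstates and correlation of their temporal parameters with
    psychometric trait scores. Implements band-pass filtering, average
    re-referencing and epoching; global field power (GFP) computation and peak
    extraction; Atomize-Agglomerate Hierarchical Clustering (AAHC) of GFP-peak
    topographies with a cross-validation criterion for the number of classes;
    backfitting of every sample by polarity-invariant spatial correlation
    (global map dissimilarity); mean duration, occurrence, coverage and
    run-to-run transition probabilities per class; Likert scale scoring with
    Cronbach's alpha, normality gating, covariate residualization and
    Bonferroni-controlled Pearson correlation tables. Ships ground-truth
    generators for synthetic microstate EEG and questionnaire cohorts so the
    whole chain can be validated against known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
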