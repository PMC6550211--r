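Package: wearstress
Title: Digital Stress Phenotyping from Wearable Physiology and Momentary Self-Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for ambulatory stress monitoring
    studies that combine multi-day wearable physiology (ECG beat series, skin
    conductance, skin temperature, accelerometry) with ecological momentary
    assessment (EMA) stress self-reports. Provides a synthetic cohort generator
    with known ground-truth stress-reactivity phenotypes, rule-based
    signal-quality indicators per channel, windowed extraction of 18
    physiological features (time- and frequency-domain heart-rate variability,
    tonic/phasic electrodermal activity, skin temperature summaries) plus an
    activity index, EMA label propagation and quality/activity filtering,
    leave-one-subject-out random-forest stress classification with
    FDR-supervised feature selection, per-subject F1 phenotype grouping,
    dynamic-range analysis, and state-wise median-difference statistics with
    Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
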