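Package: microdyn
Title: Resting-State EEG Microstate Dynamics and Band-Power Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for resting-state EEG group studies:
    deterministic preprocessing (channel selection, zero-phase band-pass,
    resampling, average reference, amplitude-based epoch rejection),
    microstate segmentation by polarity-invariant (modified) k-means on
    global-field-power peaks with GEV-maximising restarts, two-level
    (individual to group) clustering with canonical A-D labelling,
    back-fitting and the standard dynamics features (mean duration,
    occurrence, coverage, transition probabilities), Welch absolute band
    power with theta/beta ratio, group decomposition of subject-by-channel
    power matrices by extended Infomax ICA with Bonferroni-corrected
    loading tests, a two-stage statistical battery (two-way ANOVA
    interaction, post-hoc t tests, chi-square, Kruskal-Wallis), and
    SVM-RFE classification in stratified five-fold cross-validation.
    Includes a synthetic-cohort generator with planted microstate dynamics
    and band-power effects so every stage can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
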