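Package: egoflow
Title: Simulation and Analysis of Wide-Field Optic-Flow fMRI Experiments
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying egomotion selectivity in human visual cortex
    with synthetic data: wide-field three-dimensional flow-field stimulus
    simulation (translational, circular, radial, spiral, random and static
    dot fields with limited-lifetime dots, logarithmic speed scaling and
    periodic direction reversals), event-related and block experimental
    designs, synthetic BOLD time series and volumes with known ground truth,
    first-level general linear model estimation with AR(1) prewhitening and
    discrete-cosine high-pass filtering, FDR and cluster-extent thresholding,
    region-of-interest definition including the ipsilateral-response rule
    that separates MST+ from MT, the motion-coherence (MC/MI) coefficient
    with repeated-measures ANOVA, and phase-encoded retinotopy analysis
    (stimulus-frequency F ratio, response phase, visual field sign).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
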