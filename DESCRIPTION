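Package: bacadhere
Title: Mechanically Mediated Bacterial Adhesion on Soft Films
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models and simulates bacterial adhesion on hydro-softened
    polymer thin films. Couples JKR contact mechanics with a Griffith
    energy-balance criterion to compute substrate-specific adhesion
    thresholds, evaluates extended-DLVO (Lifshitz-van der Waals,
    electrostatic double-layer, Lewis acid-base) bacterium-surface
    interaction energy profiles, and runs a stochastic binary-grid
    adhesion simulation driven by logistic population growth. Includes a
    watershed-based SEM micrograph quantification pipeline (preprocessing,
    adaptive thresholding, particle morphometrics, single/aggregate
    classification, coverage-based count scaling), a ground-truthed
    synthetic micrograph generator, and the study's statistical
    comparisons (pooled t test, balanced two-way ANOVA).
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
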