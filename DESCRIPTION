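Package: fireflyQSRR
Title: Firefly-Algorithm Descriptor Selection with Support Vector
    Regression for Retention Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative structure-retention relationship (QSRR) modeling
    of reversed-phase HPLC retention factors. Couples a binary firefly
    swarm wrapper for molecular-descriptor selection to epsilon-insensitive
    support vector regression with a radial-basis-function kernel, using
    cross-validated RMSE as the selection fitness. Ships the full
    validation suite used in QSRR practice: leave-one-out and
    leave-10%-out cross-validation, external-test metrics, Spearman rank
    fidelity, Y-randomization with the cRp^2 statistic, Williams-plot and
    Hotelling T^2 applicability-domain analysis, and augmented
    partial-residual / Durbin-Watson linearity screening. Includes
    packaged quinolone and sulfonamide retention-factor fixtures and a
    synthetic-data generator emulating descriptor matrices with correlated
    nuisance blocks and a planted smooth nonlinear signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    lmtest,
    withr
Config/testthat/edition: 3
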