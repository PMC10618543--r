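Package: bcgdyn
Title: Personalized Dynamics of Intravesical BCG Immunotherapy for Bladder Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a six-compartment impulsive ordinary-differential-equation
    model of intravesical Bacillus Calmette-Guerin (BCG) immunotherapy for
    non-invasive bladder cancer, in which weekly instillations are modeled as
    Dirac-like pulses and model parameters are personalized across 72
    socio-demographic patient groups (age, gender, smoking, weight). Provides
    equilibrium and linear-stability analysis, a three-step fitting procedure
    for sparse two-timepoint clinical data (per-group gradient descent with
    five-point-stencil gradients, nearest-neighbour-gated synthetic
    augmentation, and cross-validated pipeline selection mapping
    socio-demographics to parameters), virtual-patient cohort generation, and
    evaluation utilities comparing the personalized model against a pooled
    variant and a legacy continuous-instillation model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    randomForest
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
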