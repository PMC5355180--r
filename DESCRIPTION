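Package: fertdyn
Title: Fertilization Kinetics and pH Sensitivity Analysis for Sea Urchin
    Sperm-Dilution Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for laboratory fertilization trials of
    broadcast-spawning sea urchins under seawater pH treatments.  Scores
    vial-level egg counts into total, abnormal and normal fertilization
    proportions; solves the seawater CO2 system (pCO2, DIC, carbonate ion,
    aragonite saturation) from pH on the total scale and total alkalinity;
    evaluates a mechanistic fertilization-kinetics model with polyspermy
    blocking by Gauss-Legendre quadrature with an ODE cross-check; fits
    site-by-treatment sperm-egg interaction and polyspermy-block rates in a
    hierarchical Bayesian beta-binomial framework; fits flexible cubic
    logit fertilization functions as binomial mixed models with
    likelihood-ratio tests, sperm-requirement metrics and parametric
    bootstrap contrasts; and simulates complete trial datasets with
    pair-level heterogeneity for calibration and power checks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    deSolve,
    pracma,
    lme4,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
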