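Package: prepkpd
Title: Linked Plasma-Intracellular Pharmacokinetics of Tenofovir and
    Emtricitabine with dNTP Pool Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population pharmacokinetic-pharmacodynamic model of oral
    tenofovir disoproxil fumarate / emtricitabine (TDF/FTC): two-compartment
    plasma kinetics linked to intracellular tenofovir-diphosphate and
    emtricitabine-triphosphate in peripheral blood mononuclear cells through
    a hybrid first-order-formation / saturation / recycling model, and onward
    to the endogenous deoxynucleoside triphosphate (dNTP) pool through an
    indirect-response Emax model. Provides simulation of arbitrary dosing
    regimens, virtual-population sampling with lognormal between-subject
    variability and exponential or proportional residual error, a synthetic
    clinical-trial generator with LLOQ censoring, visual-predictive-check
    style coverage diagnostics, sequential-link parameter estimation,
    closed-form and simulation-based half-life metrics including the
    operational multiple-dosing half-life, and Monte-Carlo simulation of
    analog:dNTP molar ratios under on-demand pre-exposure prophylaxis
    dosing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
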