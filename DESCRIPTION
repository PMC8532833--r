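Package: hfimdesign
Title: Design and Validation of Multi-Drug Hollow-Fiber Infection Model
    Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing hollow-fiber infection model (HFIM)
    experiments that reproduce the pharmacokinetics of several antibiotics
    with distinct elimination half-lives at the same time, using the
    parallel supplemental-reservoir layout (one diluent line and one
    supplemental tank per drug, all feeding a shared central vessel at
    equal flow).  Computes the hardware setup and dosing plan from
    per-drug targets (unbound Cmax, half-life, dosing interval), simulates
    the resulting two-compartment concentration-time profiles both by an
    exact piecewise closed form and numerically, generates synthetic assay
    observations with multiplicative lognormal noise on the duplicate
    sampling design, fits a one-compartment model with zero-order infusion
    input to observed data, derives half-life and AUC24 with confidence
    intervals, and checks the fitted profiles against targets with the
    standard within-20-percent acceptance rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
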