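Package: sunidose
Title: Model-Informed Precision Dosing for Sunitinib from Sparse
    Therapeutic Drug Monitoring Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian dose individualization for sunitinib and its active
    metabolite N-desethyl sunitinib in patients monitored by therapeutic
    drug monitoring (TDM). Implements a closed-form two-compartment oral
    absorption model for both analytes, conditional-distribution
    (posterior) sampling of individual pharmacokinetic parameters from
    sparse plasma samples under a log-normal population prior with
    combined proportional and additive residual error and left-censored
    handling of below-quantification measurements, simulation of
    steady-state trough concentrations and AUC, and grid-search dose
    recommendation against trough (50-100 ng/mL) or AUC (1200-2150
    ng/mL.h) therapeutic windows for total sunitinib (parent plus
    metabolite). Also provides a synthetic virtual-patient cohort
    generator and the cohort analytics used to compare model-based with
    clinical-sign-based dose tailoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
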