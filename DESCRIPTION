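Package: tobradose
Title: AUC24-Guided Tobramycin Dosing and Population Pharmacokinetics in
    Children with Cystic Fibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a one-compartment population pharmacokinetic model of
    intravenous tobramycin in children with cystic fibrosis, with clearance
    scaled by allometric weight, renal maturation (postmenstrual-age Hill
    function) and estimated glomerular filtration rate (modified Schwartz).
    Provides covariate-based clearance and volume prediction, individualized
    once-daily dose selection targeting a steady-state AUC24 with institutional
    dose caps, Monte-Carlo probability-of-target-attainment simulation across
    pediatric age strata, synthetic cohort and therapeutic-drug-monitoring data
    generation, and nonlinear mixed-effects estimation by per-subject Laplace
    approximation with M6 handling of below-quantification observations and
    likelihood-ratio forward covariate selection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
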