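Package: cipropkpd
Title: Population Pharmacokinetic-Pharmacodynamic Modelling of Ciprofol in
    Elderly Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for population pharmacokinetic-pharmacodynamic (PopPK/PD)
    analysis of the intravenous anaesthetic ciprofol in elderly surgical
    patients. Implements a linear three-compartment disposition model with an
    effect-site compartment and a sigmoid Emax bispectral-index (BIS) model,
    solved exactly for piecewise-constant infusion input; log-normal
    inter-individual variability with proportional (concentration) and
    additive (BIS) residual error; first-order conditional estimation with
    interaction (FOCE-I) for nonlinear mixed-effects fitting; stepwise
    covariate modelling with chi-squared objective-function gates; model
    qualification by conditional weighted residuals, nonparametric bootstrap
    and prediction-corrected visual predictive checks; and Monte Carlo
    simulation of candidate infusion regimens against a BIS 40-60 sedation
    target. A synthetic-study generator reproduces the clinical design
    (elderly demographics, weight-based bolus plus maintenance infusion,
    arterial sampling schedule) so that every analysis is reproducible from
    code and a seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
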