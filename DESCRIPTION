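Package: piperaq
Title: Population Pharmacokinetics of Piperaquine with Transit-Compartment
    Absorption and Monte Carlo Mapped Power
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonlinear mixed-effects modelling of piperaquine plasma
    concentrations after weight-based three-day oral dosing in adults with
    uncomplicated falciparum malaria.  Implements the three-compartment
    disposition model with transit-compartment absorption, fixed allometric
    scaling, between-subject and between-occasion variability, and a linear
    dose-occasion effect on relative bioavailability; a first-order
    conditional estimation (FOCE-I) likelihood engine with censored-data (M3)
    support and per-subject objective-function contributions; stepwise and
    full covariate modelling; simulation of the original rich-sampling study
    design; visual predictive checks, stratified nonparametric bootstrap and
    post hoc secondary parameters; and a modified Monte Carlo mapped power
    procedure relating covariate effect size to detection power at the
    original study size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
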