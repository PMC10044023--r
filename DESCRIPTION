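Package: ceftapk
Title: Population Pharmacokinetics and PK/PD Target Attainment of
    Ceftazidime on General Wards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for population-pharmacokinetic analysis of ceftazidime in
    adult ward patients and for beta-lactam PK/PD target-attainment work.
    Provides an analytic one-compartment infusion model with renal-function
    covariates, nonlinear mixed-effects estimation (Laplace approximation)
    with stepwise covariate selection and nonparametric bootstrap, empirical
    Bayes individual parameters, exact time-above-MIC and AUC computation,
    Monte Carlo probability-of-target-attainment simulation, prediction-
    corrected visual predictive checks, and a synthetic-cohort generator that
    emulates the dosing, sampling and renal-function structure of a ward
    cohort so the whole pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
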