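Package: ppipkpd
Title: Mechanism-Based Population PK/PD Modelling of Intravenous Proton Pump
    Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mechanism-based population pharmacokinetic and
    pharmacodynamic analysis of intravenous proton pump inhibitors, with
    ilaprazole as the reference compound. Implements a two-compartment
    infusion pharmacokinetic model with body-weight and sex covariates, a
    gastric-acid pharmacodynamic system coupling H+/K+-ATPase turnover with
    irreversible drug inactivation, a circadian nocturnal acid surge and
    meal-dilution forcing, nonlinear mixed-effects estimation (FOCE-I /
    Laplace with mu-referencing), empirical Bayes individual estimates,
    visual predictive checks, virtual-trial simulation, and dose-regimen
    comparison including dose-ceiling analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
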