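Package: celiacqsp
Title: Quantitative Systems Pharmacology Model of the Celiac Disease Immune
    Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A kinetic model of the innate and adaptive immune response to
    dietary gluten in celiac disease, formulated as a 16-state ordinary
    differential equation system over a reaction network (gluten transport
    and deamidation by tissue transglutaminase, epithelial activation,
    zonulin and interleukin-15 signalling, intraepithelial lymphocyte and
    antigen-presenting cell activation, T-cell driven antibody production).
    Provides steady-state and transient simulation, normalized antibody and
    villous-area observables, diet-switch protocols, in-silico drug
    interventions (TG-2 inhibitor, anti-IFN-gamma, anti-IL-15, permeability
    inhibitor, DQ2-blocking peptide analogues), an EC50-ratio sensitivity
    scan, parameter estimation by Hooke-Jeeves pattern search with
    profile-likelihood confidence intervals, confidence-interval robustness
    sampling, and SBML export of the reaction network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
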