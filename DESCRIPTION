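Package: phoregulon
Title: Deterministic and Stochastic Modelling of the Escherichia coli
    PhoR/PhoB Phosphate Starvation Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action modelling of the Escherichia coli Pho regulon:
    a 29-reaction chemical reaction network for the PhoR/PhoB
    two-component system and the PhoA/PhoB promoters, with deterministic
    (ODE) and exact stochastic (Gillespie direct method) simulation,
    bounded multi-start least-squares calibration against reporter time
    courses, external-phosphate and promoter-design fold-change scans,
    AUC-based local sensitivity analysis, and a synthetic-data generator
    for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
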