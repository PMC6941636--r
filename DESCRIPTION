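Package: recurjoint
Title: Joint Frailty Models for Multiple Types of Recurrent Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Joint modelling of two types of recurrent events (for example
    local tumour recurrence and distant metastasis after breast-cancer
    surgery) with correlated log-normal subject-level frailties, an optional
    terminal event, penalized marginal-likelihood estimation with M-spline
    baseline hazards integrated over the random effects by Gauss-Hermite
    quadrature, Wald hazard-ratio inference, Kaplan-Meier disease-free
    survival with Greenwood standard errors, cohort descriptives, and a
    calibrated synthetic-cohort generator with known ground truth for
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
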