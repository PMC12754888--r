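Package: vaxdce
Title: Discrete Choice Experiments for Vaccine Preference and Hesitancy Studies
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and analysing discrete choice experiments
    (DCEs) on vaccine uptake. Generates D-optimal paired choice designs from
    an attribute grid (full factorial enumeration, modified Fedorov exchange,
    random blocking, dominance-based trap tasks), simulates synthetic
    respondents with covariates, latent hesitancy and inattention, fits
    conditional logit models by from-scratch Newton-Raphson maximum
    likelihood, and computes willingness-to-pay ratios with delta-method
    intervals, relative attribute importance, and opt-out-based vaccine
    hesitancy metrics including logistic regression on respondent covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    survival,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
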