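Package: raspweib
Title: Repetitive Acceptance Sampling Plans for Weibull Lifetimes under
    Indeterminacy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, evaluation and execution of time-truncated repetitive
    acceptance sampling plans (RASP) for Weibull-distributed lifetimes under
    neutrosophic indeterminacy. Computes operating-characteristic curves and
    average sample numbers for attribute plans (n, c1, c2), solves the exact
    constrained integer minimization of the expected sample number at given
    producer and consumer risks, termination ratio, Weibull shape, mean ratio
    and indeterminacy level, and generates the corresponding design tables.
    Includes maximum-likelihood fitting and goodness-of-fit comparison of
    candidate lifetime models (Weibull, odds Weibull, Nadarajah-Haghighi,
    exponentiated Nadarajah-Haghighi), a truncated-life-test decision
    procedure, Monte-Carlo verification of the analytic OC/ASN, and a worked
    COVID-19 daily death-ratio example (Italy, April-July 2020).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
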