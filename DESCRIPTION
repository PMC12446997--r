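Package: dceacvd
Title: Distributional Cost-Effectiveness Microsimulation of Medicaid
    Expansion and Cardiovascular Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An annual-cycle Monte Carlo Markov-chain microsimulation of
    myocardial infarction, stroke and death in a synthetic nonelderly US
    adult population, with an economic layer (out-of-pocket versus
    third-party cost redistribution, productivity and administration
    costs) and a distributional cost-effectiveness analysis layer
    (incremental net health benefit, Atkinson equally distributed
    equivalent health, equity-efficiency plane, probabilistic and
    deterministic sensitivity analysis). Used to study the efficiency and
    equity of Medicaid expansion in reducing cardiovascular disease
    outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
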