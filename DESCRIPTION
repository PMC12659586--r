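Package: trialrep
Title: Assessing Trial Representativeness Against Routinely Treated Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how representative randomised-trial
    populations are of patients treated in routine care. Implements
    emulation of machine-readable trial eligibility criteria against coded
    electronic health records, multimorbidity phenotyping from a
    57-condition registry with chronic kidney disease defined from
    estimated glomerular filtration rate (CKD-EPI 2009), Poisson and
    negative-binomial comorbidity-count distribution fitting with
    parametric-bootstrap goodness of fit, observed/expected standardised
    event ratios transported from community-fitted fractional-polynomial
    rate models with Monte-Carlo confidence intervals, piecewise-linear
    (acute/chronic) eGFR total-slope estimation by mixed models, and a
    synthetic-data generator that emulates linked primary care, hospital
    and mortality records together with trial baseline and outcome tables
    under known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
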