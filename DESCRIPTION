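Package: causalprev
Title: Semi-Parametric Estimation of Marginal Prevalence Differences in
    Observational Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the marginal difference in outcome
    prevalence attributable to a binary exposure from cross-sectional
    cohort data, motivated by studies of combined oral contraceptive use
    and cervical precancer (CIN2+) in HIV care cohorts. Provides a
    structural-causal-model cohort simulator with known counterfactual
    truth, causal directed acyclic graph utilities (d-separation, the
    backdoor criterion, minimal sufficient adjustment sets), chained
    multiple imputation of missing confounders with Rubin's-rule pooling,
    three estimators of the marginal prevalence difference
    (g-computation, stabilized inverse probability of treatment
    weighting, and targeted maximum likelihood estimation), bootstrap and
    influence-curve inference, positivity diagnostics, and a config-driven
    pipeline reproducing a main and a sensitivity analysis end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
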