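Package: psmcea
Title: Partitioned Survival Cost-Effectiveness Modelling for First-Line
    Immunotherapy in Malignant Pleural Mesothelioma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A three-state (progression-free, progressed, dead) partitioned
    survival model comparing first-line nivolumab plus ipilimumab against
    pemetrexed-platinum chemotherapy for unresectable malignant pleural
    mesothelioma, from the Chinese healthcare system perspective. Provides
    six parametric survival families with right-censored maximum-likelihood
    fitting and AIC/BIC model selection, pseudo individual patient data
    reconstruction from digitised Kaplan-Meier curves and number-at-risk
    tables (Guyot algorithm), a monthly-cycle discounted cost and QALY
    engine with a detailed drug-acquisition cost model, one-way (tornado)
    and probabilistic sensitivity analyses with cost-effectiveness
    acceptability curves, threshold-price search by bisection, and a
    synthetic trial-arm generator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    yaml
Suggests:
    flexsurv,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
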