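Package: psmcea
Title: Partitioned-Survival Cost-Effectiveness Modelling for First-Line
    Pleural Mesothelioma Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (progression-free, progressed, dead)
    partitioned-survival cohort model for the cost-effectiveness of
    pembrolizumab plus platinum-pemetrexed chemotherapy versus chemotherapy
    alone in untreated advanced pleural mesothelioma, from the Chinese
    healthcare system perspective.  Includes closed-form survival machinery
    for the eight parametric families used in health-technology assessment,
    reconstruction of pseudo individual-patient data from digitized
    Kaplan-Meier curves with number-at-risk tables, maximum-likelihood
    fitting with AIC/BIC model selection, a synthetic trial generator,
    deterministic and probabilistic sensitivity analysis (tornado diagrams,
    cost-effectiveness acceptability curves), and incremental net-benefit
    statistics at a willingness-to-pay threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    flexsurv,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
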