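Package: pbpkddi
Title: Reduced Whole-Body PBPK Modelling of Transporter-Mediated
    Drug-Drug Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale physiologically-based pharmacokinetic (PBPK) engine
    for transporter-mediated drug-drug interactions. Implements a reduced
    whole-body flow-limited model (gut lumen and tissue, portal vein, liver,
    kidney, arterial and venous plasma, lumped rest-of-body, urine and feces
    sinks) with Michaelis-Menten efflux by the ABCB1 (P-glycoprotein) and
    ABCG2 (BCRP) transporters, perpetrator-driven transporter induction via a
    turnover model and competitive inhibition via apparent-Km scaling,
    Rodgers-Rowland tissue partitioning, non-compartmental exposure metrics,
    and the standard PBPK model-qualification statistics (MRD, GMFE, AFE,
    RMSE, fold-error classification, DDI exposure ratios). Ships calibrated
    linezolid (victim) and rifampin (perpetrator) compound models, a
    pre-registered scenario runner covering monotherapy, standard-dose and
    high-dose rifampin co-administration, and a synthetic clinical-study
    generator with lognormal between-subject variability for evaluating the
    metric suite without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
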