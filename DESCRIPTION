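Package: pclnet
Title: Plasma Cholesterol Lowering Lesion Networks: Gene Sets, Risk
    Enrichment, CLR Master Regulators, and Perturbation Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for studying transcriptional responses of
    atherosclerotic lesions to plasma cholesterol lowering (PCL).  Defines
    stage-specific PCL-responsive and regression-reactive gene sets by
    differential expression (Benjamini-Hochberg or empirical-null local
    false discovery rates), measures enrichment of inherited coronary
    disease risk in those sets via cis-eSNP detection, linkage
    disequilibrium expansion and a matched random-set resampling null,
    infers transcription-factor regulatory co-expression networks with the
    context likelihood of relatedness (CLR) procedure and ranks hub TFs as
    candidate master regulators, validates networks against siRNA
    knockdown screens with hypergeometric specificity tests and
    cholesterol-ester readouts, and scores plaque stability from
    histology.  Every input can be simulated with known planted ground
    truth, so the whole chain is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
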