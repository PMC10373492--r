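Package: dnadduct
Title: Untargeted DNA Adductomics by DIA Neutral-Loss Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An untargeted DNA-adductomics workflow for data-independent
    acquisition (DIA) LC-HRMS data. Putative 2'-deoxyribonucleoside adducts
    are detected by pairing MS1 precursors with DIA MS2 fragments showing
    the characteristic 116.0473 Da 2'-deoxyribose neutral loss, confirmed
    and integrated against a cross-sample master list, semi-quantified by
    normalisation to the 2'-deoxyguanosine peak area, annotated with
    constrained elemental-composition enumeration, and analysed with the
    multivariate statistics used in exposure studies (Pearson correlation
    screens, PERMANOVA/PERMDISP, SIMPER, OPLS-DA with VIP and Q2, ROC, and
    volcano-style group contrasts). A synthetic-data module generates DIA
    runs with planted adducts and study-level adduct-by-sample tables with
    planted group effects and contaminant correlations, so that every stage
    is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mzR,
    vegan,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
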