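Package: pcrconcord
Title: Concordance of RT-qPCR and Immunohistochemistry for Breast-Cancer
    Biomarkers and Prediction of Pathological Complete Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing RT-qPCR gene expression (40-delta-delta-Cq
    relative quantification of ESR1, PGR, MKI67 and ERBB2 against the B2M and
    CALM2 reference genes) with visual and digital-image-analysis
    immunohistochemistry scoring of the corresponding proteins in breast
    cancer. Includes triplicate Cq aggregation with quality control,
    calibrator-corrected normalization, biomarker dichotomization by
    immunoreactive score and percent-positivity rules, method-concordance
    statistics (positive/negative/overall percent agreement, Spearman rank
    correlation, exact contingency tests), sensitivity-constrained ROC
    cutoff selection for predicting pathological complete response after
    neoadjuvant therapy, and a Gaussian-copula synthetic cohort generator
    that emulates the joint mRNA/protein/outcome structure of such studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
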