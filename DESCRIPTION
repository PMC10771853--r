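Package: methresp
Title: Peripheral-Blood DNA Methylation Classifiers of Anti-TNF Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for epigenome-wide association studies of
    therapy response in rheumatoid arthritis from whole-blood Illumina
    EPIC-style methylation data. Provides a seeded synthetic-cohort generator
    with known ground truth (blood cell mixtures, planted response-associated
    CpGs, SNP-like probes, covariate effects, DAS28 trajectories), beta/M-value
    conversion and allosome filtering, gap-based detection of SNP-affected
    probes, reference-based cell-type deconvolution by non-negative least
    squares, covariate-adjusted per-CpG differential methylation, gene-level
    aggregation of correlated p-values by Brown's method with loess regional
    profiles, DAS28/EULAR response labeling with cohort characteristic tables,
    and a stability-selected gradient-boosting classifier with noise-probe
    feature retention and pairwise-permutation rank aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    pracma,
    xgboost,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
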