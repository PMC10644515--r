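Package: ggnsc
Title: Single-Cell RNA and TCR Analysis of Ground-Glass-Nodule Lung Adenocarcinoma Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the bespoke computations used in
    single-cell studies of ground-glass-nodule lung adenocarcinoma spanning
    normal lung, adenocarcinoma in situ (AIS) and invasive adenocarcinoma
    (IAC): copy-number inference from expression along genomic coordinates
    with a correlation-based malignancy score; stage-associated gene
    selection with a per-gene mixed model; metacell aggregation and
    weighted-gene-co-expression module detection with trajectory
    classification across disease stages; binned-control gene-set scoring
    with dysfunction-gene selection; and paired-chain T-cell-receptor
    clonotype statistics (clonal fractions, clone-space occupancy,
    repertoire overlap, V-J usage). A synthetic-cohort generator plants
    known malignant cells, co-expression modules, functional programs and
    clonal expansions so every stage of the pipeline is testable end to end
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
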