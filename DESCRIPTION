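Package: gliopipe
Title: Expression Subtyping and SNP-Array Copy-Number Pipelines for Glioma Model Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for mouse neural-stem-cell glioma models and
    matched human cohort data. Provides generalized-log variance stabilization
    and quantile normalization of bead-array style expression matrices,
    technical-duplicate collapsing with correlation QC, fold-change based
    selection of deregulated genes and rescue classification in a second
    genotype, cross-species nearest-centroid GBM subtype assignment with a
    bootstrap simulation test, SNP-array Log-R-Ratio GC-waviness correction by
    variance minimization, changepoint segmentation with SD-undo merging and
    five-state copy-number calling, rank-based cohort z-score comparisons, and
    a synthetic-data module that plants known truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
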