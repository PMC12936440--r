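Package: budnet
Title: Environmental Traits, Co-Expression Modules and DAM/SVP Regulatory
    Networks in Dormant-Season Bud Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparing winter transcriptional programs of
    tree bud organs (flower versus vegetative buds) across a chilling time
    course. Computes Utah-model chilling units and photoperiod (day length)
    traits, normalizes RNA-seq count matrices (TMM), removes batch structure,
    identifies differentially expressed genes, classifies organ-biased genes
    with a linear model and projection PCA, detects weighted co-expression
    modules and correlates module eigengenes with environmental cues, builds a
    reduced top-k thresholded co-expression graph, and infers regulator-target
    networks for DAM/SVP MADS-box transcription factors from tree-ensemble
    importances with dimer and BiFC annotation. Includes a synthetic-data
    generator with planted ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ranger
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    mclust,
    optparse,
    knitr
Config/testthat/edition: 3
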