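Package: miRTargetCor
Title: Integrative miRNA-mRNA Negative-Correlation Target Analysis for
    Hepatic Stellate Cell Quiescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct miRNA-mRNA repression networks from paired
    quiescent and culture-activated hepatic stellate cell (HSC) expression
    profiles. Implements comparative-Ct arithmetic (-dCt normalization to a
    reference small RNA, 2^-ddCt relative expression), detection filtering for
    TaqMan-style miRNA arrays, fold-change and Student t-test differential
    classification with cell-type enrichment rules against hepatocyte and
    liver sinusoidal endothelial cell references, all-pairs Pearson
    correlation of deregulated miRNAs against deregulated mRNAs with
    Benjamini-Hochberg false discovery rate control, intersection with a
    sequence-based target-prediction table, and network-level summaries
    (targets per miRNA, quiescence-associated miRNA panels, target coverage,
    most-targeted genes). A synthetic-data module plants a known repression
    network in paired-donor designs so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: GeneExpression, Transcriptomics, Regulation, Network,
    DifferentialExpression
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'diffexpr.R'
    'expression-prep.R'
    'integration.R'
    'miRTargetCor-package.R'
    'pipeline.R'
    'simParams.R'
    'simulate.R'
    'summarize.R'
    'tables-io.R'
    'utils.R'
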