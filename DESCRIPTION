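Package: complexSV
Title: Orthogonal Evidence and Cohort Analyses for Complex Structural
    Variants in Tumor Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing complex structural variants (cSVs)
    such as extrachromosomal DNA (ecDNA) and breakage-fusion-bridge (BFB)
    amplifications in tumor genomes. Provides a statistical framework that
    scores candidate amplicons against Hi-C contact matrices (cis and
    trans), a sliding-window chromothripsis caller, ploidy-aware gene-level
    copy-number calling, breakpoint-level similarity scoring for
    cross-sample convergence, permutation tests for regulatory-element
    enrichment, nested linear models for expression beyond copy number, and
    neighbor-joining phylogenies from somatic mutation profiles. Synthetic
    data generators with known ground truth make every stage testable
    without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    IRanges,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
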