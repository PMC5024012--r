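Package: coexmap
Title: Modular Transcriptome Analysis with Coexpression Groups and Signed
    Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for delineating the modular organization of a multi-tissue
    transcriptome from designed two-colour microarray (or similar log2
    intensity) experiments. Genes are screened for distributional assumptions
    and classified as tissue-variable or invariant with a balanced mixed-model
    ANOVA using expected-mean-square F ratios; high-confidence variable genes
    are clustered into expression modules by soft-thresholded correlation and
    topological overlap, each module is split into two anticorrelated
    coexpression groups summarised by eigengenes, and remaining genes are
    assigned by template matching. Hypergeometric over- and
    under-representation of gene sets across arbitrary partitions, unweighted
    signed correlation-threshold networks with tie-aware hub ranking and
    scale-free fit diagnostics, and a seasonal (species x time) analysis that
    integrates temporal clusters with tissue-based groups to call earlywood
    and latewood genes complete the pipeline. A synthetic-data generator with
    planted modules, invariant genes, assumption violators and hub genes
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nortest,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
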