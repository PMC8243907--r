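Package: spatialmeth
Title: Spatial Mapping of Tumor Progression from DNA Methylation Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the spatial progression of a multi-region tumor
    from methylation-array beta values: selection of the most variable CpG
    probes, unsupervised hierarchical clustering of samples, a
    neighbor-joining sample phylogeny with an anatomical spread path,
    pairwise differential methylation with Benjamini-Hochberg FDR control,
    low-resolution copy-number profiling from array log2 intensity ratios,
    MGMT promoter methylation calls, reference-based microenvironment
    deconvolution, and preranked gene-set enrichment. Includes a
    clonal-evolution cohort simulator with planted ground truth so every
    stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    cluster,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    fgsea,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
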