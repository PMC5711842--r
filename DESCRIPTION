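Package: segscreen
Title: Phenotypic-Vector Analysis for Modular Zebrafish Segmentation Screens
Version: 0.1.0
Authors@R:
    person("Screen", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multi-parameter ordinal phenotype screens of
    the kind used to find small molecules that perturb embryonic segmentation
    in zebrafish. Treatments are described by 12-dimensional phenotypic
    vectors (six general-morphology and six segmentation parameters, each
    scored 0-3 against untreated controls of the same genotype). The package
    provides a validated score-table data model with embryo-level consensus
    calling, replicate quality control (pointwise Pearson correlation and
    normalized Hamming distance), hit ranking by a modified strictly
    standardized mean difference (SSMD) and by the segmentation-morphology
    mean difference with the standard exclusion filters, compound-level hit
    calling with a wild-type reproducibility filter and genotype
    (enhancer/suppressor) and concentration profiling, hierarchical
    clustering of phenotypic vectors with correlation distance and average
    linkage, Newick dendrogram export, concentration-dependence summaries
    with a two-way ANOVA on lethal counts, bipartite compound-parameter
    network export (SIF/GraphML), and a fully seeded synthetic screen
    generator with planted hit classes and ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
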