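Package: GTseqPanel
Title: Design, Selection and QC of GT-seq Microhaplotype Panels for Temporal
    Genetic Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for developing Genotyping-in-Thousands by sequencing
    (GT-seq) amplicon panels from temporal microhaplotype data. Starting from
    a genotype matrix of time-stamped collections and a reference genome, the
    package filters loci (depth, missingness, Hardy-Weinberg, linkage
    disequilibrium), trims SNPs for primer and probe compatibility, screens
    candidate primer pairs for off-target annealing, scores candidate locus
    subsets by how well they track temporal genetic change (per-locus temporal
    F_ST, diversity statistics, permutation-tested pairwise F_ST, DAPC
    centroid distances), and quality-controls multiplexed amplicon sequencing
    rounds: read classification against primer-interaction artifacts,
    probe-based allele counting, maximum-likelihood microhaplotype genotyping,
    concordance, locus-removal recommendations and a stopping rule. A
    Wright-Fisher simulator generates temporal genotype series, reference
    sequences with embedded loci and amplicon read pools with known truth so
    the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    MASS,
    vegan,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
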