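Package: epiSeeker
Title: Two-Stage Ant Colony Optimization for Detecting Epistatic
    Interactions in Case-Control Studies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects epistatic (multi-SNP) interactions in case-control
    genotype panels with a two-stage ant colony optimization search
    (AntEpiSeeker). Stage one runs pheromone-guided sampling of SNP sets at
    two set sizes to harvest highly suspected sets and top-pheromone loci;
    stage two exhaustively tests all interaction-sized subsets of the
    harvest with a Pearson chi-square test on genotype-combination by
    status contingency tables, followed by an overlap-pruning procedure
    that minimizes false positives. Includes a simulator for two-locus
    penetrance models (additive, multiplicative and threshold epistasis
    with calibrated marginal effect sizes, Hardy-Weinberg genotypes and
    tag-marker linkage disequilibrium), null-panel generation, and
    evaluation utilities for detection power, null false-positive rates
    and true-positive/false-discovery rates on multi-interaction panels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
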