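Package: hybridTS
Title: Training Set Optimization for Genomic Selection in Hybrid Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing training sets for genomic prediction in
    hybrid crop populations under a GBLUP model with additive and dominance
    effects. Implements additive and dominance marker coding, standardized
    genomic relationship matrices, three training-set selection criteria
    (a ridge-regression mean squared prediction error criterion, a
    heuristic mean coefficient-of-determination criterion, and an
    A-optimality-like genomic-variance ranking), a steepest-ascent exchange
    optimizer over fixed-size subsets, closed-form BLUP of genotypic values
    for training and candidate individuals, top-k ranking evaluation
    metrics (NDCG, Spearman rank correlation, rank-sum ratio) with a
    relative-improvement summary, and a simulator of hybrid genotypes and
    phenotypes that runs the full evaluation study on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
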