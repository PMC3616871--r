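Package: phylomer
Title: Phylome-Based Phylogenomic Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylome-scale phylogenomics: species-overlap labeling of
    gene-tree nodes as duplications or speciations, ortholog and paralog
    cataloguing, TreeKO-style decomposition of multi-copy gene trees into
    speciation-only subtrees, LCA reconciliation and duplication dating onto
    species-tree lineages with redundancy merging and per-lineage duplication
    rates, supertree reconstruction under split-fit and gene-tree duplication
    parsimony criteria, per-bipartition gene-tree support, strict one-to-one
    ortholog selection with partitioned supermatrix concatenation and
    amino-acid compositional-bias PCA, a protein likelihood engine (empirical
    exchangeability models, discrete gamma plus invariant sites, Felsenstein
    pruning, branch-length optimization, AIC model selection), RELL/KH/SH and
    approximately-unbiased topology tests, homology-hit filtering and phylome
    combination, and a gene birth-death phylome simulator with planted ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
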