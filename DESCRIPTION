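Package: paraconv
Title: Detection of Gene Conversion Between Paralogous Genes by
    Sliding-Window Maximum Likelihood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects conversion between paralogous genes (such as the
    bacterial class-I release factors RF1 and RF2) from a protein or
    nucleotide alignment of paralog pairs.  A sliding-window maximum
    likelihood scan contrasts the no-conversion topology (paralogs
    reciprocally monophyletic) with a constrained topology uniting the
    candidate converted pair, a parametric bootstrap calibrates the
    critical log-likelihood difference for a fixed-level test, and a
    corrected t statistic on site-wise log-likelihood differences with a
    max-statistic permutation adjustment estimates the boundaries of the
    converted tract.  Includes a small maximum-likelihood engine
    (LG/WAG/GTR and two-state models with discrete-gamma rate variation,
    Felsenstein pruning, branch-length optimization, constrained tree
    search, simulation along a tree), utilities for RY recoding and G+C
    compositional screening, an anchored indel-motif classifier, and a
    synthetic-data generator that implants conversion tracts with full
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    seqinr,
    jsonlite,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
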