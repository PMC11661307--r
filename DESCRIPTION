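Package: snqtl
Title: Cell-Type-Resolved eQTL Mapping from Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping genetic regulation of gene expression at
    cell-type resolution from single-nucleus RNA-seq. Implements pseudobulk
    aggregation and Pearson-residual normalization with hidden-factor
    selection, cis-eQTL mapping with single-causal-variant fine-mapping and
    MaxCPP annotations, empirical-Bayes multivariate shrinkage of effects
    across cell types with a composite cell-type-specificity test,
    Bayesian colocalization with approximate Bayes factors, dynamic
    (pseudotime-interaction) eQTL detection with a negative-binomial mixed
    model, trans-eQTL mapping with Sidak and Benjamini-Hochberg correction,
    and cis-mediation analysis of trans effects. A seeded synthetic-data
    generator emulating donor-structured single-nucleus counts drives the
    full pipeline and its tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    glmmTMB,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
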