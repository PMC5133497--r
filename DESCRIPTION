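Package: rvexpress
Title: Expression-Weighted Rare-Variant Association Testing for Family Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-level rare-variant association testing for quantitative
    traits in family samples, with gene-expression-informed p-value
    re-weighting. Phenotypes are decorrelated through the inverse square
    root of a SNP-estimated genetic relationship matrix and residualized
    on leading stratification axes; each gene is tested with a sequential
    sum test that adaptively assigns +1/-1/0 codings to its rare variants
    before a pooled score test, with significance assessed by permutation.
    Per-gene weights are built from two Wald statistics linking gene
    burden to expression and expression to phenotype, normalized to mean
    one, and used for weighted-Bonferroni control of the family-wise
    error rate. Includes a pedigree-aware synthetic-data generator
    (gene-dropping genotypes, causative and reactive expression models)
    so the full pipeline is testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vcfR,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
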