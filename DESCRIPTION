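Package: speltpop
Title: Population Genomics and Glume-Color Genetics of Spelt Wheat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable re-implementation of a spelt/bread-wheat population
    genomics analysis: SNP filtering and classification from VCF, principal
    component and multidimensional-scaling structure analysis, folded joint
    site-frequency-spectrum construction with hypergeometric projection,
    coalescent simulation and composite-likelihood demographic model selection
    with parametric-bootstrap confidence intervals, covariate-adjusted logistic
    genome-wide association for glume color, rule-based haplotype-group
    classification of candidate MYB alleles with neighbor-joining trees and
    in-silico PCR marker validation, and relative expression quantification by
    the 2^-ddCt method. A synthetic-data module generates cohorts, phenotypes
    and allele fixtures so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    ape,
    Biostrings,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
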