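Package: poolgrm
Title: Unbiased Genomic Relationship Matrices from Low-Depth Pool Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction machinery for breeding programmes that genotype
    individuals and family pools by low-depth genotyping-by-sequencing (GBS).
    Builds allele-frequency genomic relationship matrices (GRMs) that treat a
    pool as a polyploid genotype with ploidy equal to the summed parental
    ploidy, corrects the diagonal inflation caused by binomial read-sampling
    error at low coverage depth, imputes missing allele frequencies by mean,
    k-nearest-neighbour and iterative random-forest methods, and fits GBLUP
    mixed models by REML with leave-one-out and across-set cross-validation.
    Includes a breeding-population simulator (founders, F1/F2 family pools,
    single plants, multi-parent synthetic varieties, linked scaffolds,
    depth-degraded reads and GRM-correlated phenotypes) used to validate the
    bias correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
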