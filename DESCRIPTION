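Package: gpsel
Title: Genomic Prediction with Marker Preselection in Small Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic best linear unbiased prediction (GBLUP) for small
    livestock and poultry populations, with SNP marker preselection by a
    homozygote-contrast statistic (pre-marker selection, PMS) or by
    single-marker GWAS. Provides genotype/phenotype input and quality
    control, fixed-effect phenotype correction, the VanRaden genomic
    relationship matrix, exact one-component REML by eigendecomposition,
    leave-one-out cross-validation with per-fold marker reselection,
    bootstrapped scenario comparison, and a gene-dropping simulator of an
    F2 cross between divergent founder lines for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
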