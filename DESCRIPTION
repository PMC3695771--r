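Package: semigwas
Title: Semi-Parallel Linear and Logistic Regression for Genome-Wide
    Association Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fast single-SNP association scans computed as dense matrix
    operations instead of per-SNP model fits. Quantitative traits are
    analysed by exact vectorized least squares after residualizing the
    phenotype and genotype blocks against covariates; binary traits by an
    approximate one-step weighted least-squares update from the
    covariate-only logistic fit. Includes a SNP-major chunked byte
    container for genotype dosages, a PLINK BED decoder, call-rate
    filtering with mean imputation of missing genotypes, a simulator for
    genotypes and traits, and brute-force reference fitters used to
    verify the block algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
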