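Package: plsmet
Title: Partial Least Squares Genomic Prediction for Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-trait and multi-trait partial least squares (PLS) genomic
    prediction for multi-environment plant-breeding trials. Implements the
    kernel PLS algorithm with deflation, genomic relationship kernels built
    from SNP dosages, Kronecker genotype-by-environment kernels, assembly of
    the kernel-augmented input matrix [X_E, X_g L_g, X_gE L_gE], nested
    cross-validation (random five-fold and leave-one-environment-out, with
    inner five-fold tuning of the number of latent components by normalized
    root mean squared error), and Pearson-correlation/NRMSE accuracy reports.
    Includes a synthetic potato-breeding data generator with controllable
    heritabilities, genetic correlations and genotype-by-environment variance
    for validation studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
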