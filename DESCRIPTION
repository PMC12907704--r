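Package: cfdecon
Title: Interpretable Autoencoder Deconvolution of Tumor Fraction from
    cfDNA Methylation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the tumor-derived fraction of plasma cell-free DNA
    (cfDNA) from Illumina 450K-style methylation beta-value matrices using an
    interpretable autoencoder whose two-dimensional latent space represents
    healthy and tumor mixing fractions and whose sigmoid-squashed effective
    decoder weight matrix is a learned two-population methylation atlas.
    Includes the upstream tumor-specific differentially methylated position
    (DMP) selection pipeline (beta/M-value transforms, group-means linear
    models on M-values with empirical-Bayes variance moderation, FDR control
    and a two-contrast tumor-specificity filter), a Dirichlet mixture
    simulator that fabricates training sets with known fraction labels,
    longitudinal treatment-monitoring statistics (baseline versus first
    follow-up paired t-test), and seeded synthetic-data generators so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    limma,
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
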