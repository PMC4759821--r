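Package: blockeqtl
Title: Block Mixture Models for Joint eQTL Mapping and Gene Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a Gaussian block (latent block) mixture model that
    simultaneously clusters transcripts into latent expression clusters and
    maps individuals onto latent eQTL genotypes by interval mapping in a
    two-genotype (backcross or RIL-homozygote) cross. Estimation maximises a
    per-cell composite likelihood with a two-layer EM algorithm; the number
    of clusters is chosen by a composite-likelihood BIC. Provides genome-wide
    eQTL scans with permutation-based significance thresholds, composite
    likelihood ratio tests for cluster-level, interaction and
    cluster-structure effects of an eQTL, genotype-conditional cluster
    co-expression networks, and a seeded backcross simulator for power and
    calibration studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
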