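Package: tetraqtl
Title: QTL Mapping in Multivalent Tetraploids with Double Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood mapping of quantitative trait loci (QTLs) in
    multivalent (autopolyploid) tetraploids from single fully informative
    markers in a pseudo-testcross design. Models tetrasomic co-inheritance
    through the nine observable two-locus gamete modes of Fisher's
    quadrivalent classification, so that double reduction at both the marker
    and the QTL is estimated jointly with the marker-QTL recombination
    fraction and the ten QTL genotypic values. Estimation uses an EM
    algorithm on the normal-mixture likelihood; hypothesis tests for QTL
    presence use likelihood ratios with permutation thresholds, and additive
    and dominance effects are tested through constrained EM fits. A
    simulator generates pseudo-testcross datasets under specified double
    reduction, recombination, genetic effects and heritability, and a
    replication runner summarises estimator behaviour over Monte-Carlo
    replicates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
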