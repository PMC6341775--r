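Package: hybridscan
Title: Multi-Evidence Analysis of Plant Hybrid Swarms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising putative hybrid populations from
    several independent lines of evidence: linear discriminant analysis of
    floral morphometrics with repeated k-fold cross-validation, a log R/G
    sepal-colour metric, microsatellite summary statistics, Bruvo genetic
    distances, principal coordinate ordination, distance trees, discriminant
    analysis of principal components (DAPC), supervised Bayesian admixture
    estimation with reference-only allele-frequency updating, plastid
    haplotype networks with simple indel coding, and a spherical
    range-centroid statistic for detecting clinal introgression. Includes a
    hybrid-swarm simulator with known ground truth so every stage of the
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    MASS,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
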