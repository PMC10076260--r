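Package: introscan
Title: Adaptive Introgression Scans for Admixed Crop Genepools
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end toolkit for detecting adaptive introgression
    between deeply diverged crop genepools from phased variant panels.
    Implements Li & Stephens haplotype painting against donor panels with
    per-accession EM estimation of copying parameters, window-level ancestry
    assignment, introgression-block extraction and ancestry masking,
    ancestry-masked nucleotide diversity, windowed Weir & Cockerham FST,
    FLK and haplotype-cluster (hapFLK-style) selection statistics with
    Reynolds-distance kinship, excess-introgression scans with
    sample-size-derived thresholds, putative adaptive introgressed locus
    (PAIL) calling, private inter-chromosomal linkage disequilibrium,
    genetic-load ratios, and a QST-FST comparison for quantitative traits.
    A synthetic admixed-panel generator with known ancestry tracts makes the
    whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    ape,
    phangorn,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    GenomicRanges,
    IRanges,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
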