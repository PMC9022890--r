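Package: hapsweep
Title: Spatially Aware Composite Likelihood Scans for Selective Sweeps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genome scans for selective sweeps from the haplotype frequency
    spectrum (HFS). Computes K-truncated haplotype or multilocus-genotype
    frequency spectra in sliding SNP-delimited windows, models a sweep as a
    distortion of the genome-wide spectrum whose influence decays
    exponentially with distance from a focal window, and reports a
    composite likelihood ratio statistic (Lambda) together with estimates
    of sweep softness (the number of sweeping haplotypes) and footprint
    (the decay rate of the sweep's effect) at every window. Also provides
    the non-spatial single-window likelihood ratio statistic T,
    expected-homozygosity summaries (H1, H12, H2/H1 and their
    multilocus-genotype analogues G1, G123, G2/G1), empirical threshold
    calibration from neutral replicates, outlier region calling, and a
    synthetic-data generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    vcfR,
    IRanges,
    S4Vectors,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
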