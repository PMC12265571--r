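Package: sweepscape
Title: Simulation-Based Detection and Classification of Selective Sweeps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome scans that detect and classify
    recent selective sweeps from unphased diploid genotype data. Labeled
    training data are produced by a forward-time Wright-Fisher simulator
    under hard-sweep, soft-sweep, sweep-linked and neutral models with
    configurable parameter priors and piecewise-constant demography.
    Genomic windows are summarized by twelve population-genetic statistics
    (pi, Watterson's theta, Tajima's D, diplotype counts, H1/H12/H2-H1
    homozygosity statistics, Zns, the maximum of the omega statistic, and
    moments of the pairwise-difference distribution) computed in eleven
    adjacent subwindows, normalized, and classified into five classes by a
    small neural network with validation-based early stopping. Calls are
    assigned q-values against a neutral-simulation null and the fraction
    of sweeps that are soft is estimated with a conservative
    classification-error correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
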