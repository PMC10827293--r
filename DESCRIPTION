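Package: driftscape
Title: Spatial Population Structure, f4 Clade Tests and Ancestry-Outlier
    Detection for Ancient DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying historical-period population structure from
    (pseudohaploid) ancient-DNA genotype data and from forward simulations in
    continuous space.  Implements EIGENSTRAT genotype I/O; f4-statistics with
    weighted block-jackknife covariance; qpWave-style one-component (clade)
    tests and two-component admixture fits; a full ancestry-outlier workflow
    (UPGMA clustering of pairwise dissimilarities, outlier classification,
    cross-region source attribution via model competition, migration-network
    summaries); Hudson FST on a sliding spatial grid with lowess
    isolation-by-distance curves and an overlap-aware spatial bootstrap;
    reference-space PCA with iterative outlier removal and least-squares
    projection of low-coverage genomes; a continuous-space Wright-Fisher
    simulator with Gaussian mate-choice and competition kernels, local plus
    long-range dispersal, FST-trajectory tracking and dispersal calibration;
    and a Balding-Nichols synthetic-data generator with planted migrants for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
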