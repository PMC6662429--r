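Package: nestgen
Title: Spatial and Genetic Tests of Natal Philopatry in Communally Nesting Reptiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether natal philopatry shapes nest-site selection
    in communally nesting reptiles, at three spatial scales. Provides Ripley's
    K and L-function estimates with Monte Carlo envelopes under complete
    spatial randomness, percolation-style edge thinning to delimit nest
    clusters at threshold distances, per-locus microsatellite diversity
    statistics (heterozygosity, exact Hardy-Weinberg tests, Weir-Cockerham
    F_IS with permutation tests, null-allele estimation by EM), pairwise and
    four-level hierarchical AMOVA with level-specific permutation schemes,
    Mantel tests of isolation by distance, gene-flow estimation from private
    alleles, and effective population size by linkage disequilibrium,
    heterozygote excess, and molecular coancestry. A synthetic-study
    generator produces clustered nest point patterns and family-structured
    genotypes under a tunable philopatry parameter, so every stage can be
    exercised against data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
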