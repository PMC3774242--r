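Package: pleioscan
Title: Bivariate QTL Co-Localization and Population Differentiation at a
    Pleiotropic Flowering-Time Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to map a pleiotropic quantitative trait locus jointly
    affecting water-use efficiency, growth rate and flowering time in a
    recombinant inbred line population, and to test whether functional
    variation at the underlying flowering-time locus structures natural
    populations. Implements Haley-Knott regression genome scans on a
    pseudo-marker grid with permutation thresholds, additive stepwise model
    selection and position refinement; a standardized-LOD bivariate
    co-localization statistic with a joint peak and interval; Nei and
    Weir-Cockerham FST between allele-functionality classes with
    frequency-matched resampling nulls and 50-kb-thinned regional FST;
    radial-basis-kernel imputation of allele functionality from flanking
    SNPs with k-fold and subset leave-one-out cross-validation; and
    climate/phenotype association statistics. A synthetic-data generator
    with recorded ground truth replaces the unavailable experimental
    genotypes and phenotypes, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
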