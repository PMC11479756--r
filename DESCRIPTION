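Package: morphsim
Title: Maintenance of Male Reproductive Morphs Across Genetic Architectures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Deterministic and stochastic models of the maintenance of four
    discrete male reproductive morphs (courter/parent, courter/non-parent,
    non-courter/parent, non-courter/non-parent) under mate choice, sneak
    fertilization, obligate paternal care and viability selection. Provides an
    analytical recurrence over morph frequencies with parameter-sweep tooling,
    a forward-time diploid individual-based simulator with explicit genetic
    architectures (single locus, genome-wide quantitative trait loci, or a
    non-recombining supergene), and a population-genomic statistics layer
    (heterozygosity, G_ST between morphs, Tajima's D, linkage disequilibrium,
    association scans and peak detection against the true causal loci).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
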