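Package: aimkit
Title: Ancestry-Informative Marker Selection and Haploid IBD Analysis for
    Honey Bee Population Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of haploid honey bee
    (Apis mellifera) drone sequences and for the design of reduced SNP
    panels. Implements genotype and site quality control, PLINK-style
    windowed linkage-disequilibrium pruning, a two-state hidden Markov
    model for identity-by-descent estimation between haploid genomes,
    principal-component analyses with genetic-geographic correlation
    tables, repeated random-forest ranking of ancestry-informative
    markers with an empirical random-panel null, and pedigree-based
    simulation of F1 and backcross hybrids used to stress-test a panel.
    A Balding-Nichols synthetic-population generator with queen
    pedigrees, longitudinal allele-frequency clines and controlled-IBD
    pairs provides fully scored test data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    ggplot2,
    igraph,
    ranger,
    Rcpp,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tools,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
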