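Package: baobab
Title: Introgression, Diversity, Competition and Niche Analyses for
    Island Radiations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quartet site-pattern statistics for detecting interspecific
    gene flow (Patterson's D with block-jackknife significance, the
    f4-admixture ratio and tree-wide f-branch mapping), a 100-kb window
    scan with an interval-length timing analysis of introgressed regions,
    windowed heterozygosity and runs-of-homozygosity profiling, a coupled
    logistic simulator of two competing populations, and ecological
    valence, bioclimatic envelope superimposition, Schoener's D niche
    overlap with equivalency/similarity randomization tests and
    land-area-versus-sea-level curves. Every analysis is paired with a
    seeded synthetic-data generator (a multispecies-coalescent site
    simulator with seeded introgression, genomes with planted
    low-heterozygosity tracts, island-shaped rasters and occurrence
    samplers) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    phangorn,
    MASS,
    deSolve,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
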