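Package: rohscan
Title: Runs of Homozygosity, Genomic Inbreeding and ROH Islands from
    Diploid Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) in multi-sample diploid
    genotype data with a sliding-window scan, computes the genomic
    inbreeding coefficient F_ROH, locates ROH islands shared by a large
    fraction of a population (candidate selection signatures) and
    annotates them with overlapping genes, and summarises population
    structure through identity-by-state distances and classical
    multidimensional scaling.  Includes genotype quality control
    (call-rate, minor-allele-frequency and linkage-disequilibrium
    filters, PI-HAT relatedness pruning), a multi-population genotype
    simulator with planted autozygous segments for validation, and an
    end-to-end pipeline producing tidy per-sample and per-population
    report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    jsonlite,
    generics,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
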