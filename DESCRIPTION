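Package: mutaccum
Title: Somatic Mutation Accumulation Analysis for Clonal Organoid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing somatic mutation accumulation in clonally
    expanded stem-cell genomes (e.g. intrahepatic cholangiocyte organoids).
    Classifies somatic variants from VCF files into COSMIC mutation-context
    catalogs (SBS96, DBS78, ID83) and a 16-category structural-variant
    schema, refits per-clone spectra to signature definitions by
    non-negative least squares, estimates per-group mutation accumulation
    rates with zero-intercept linear mixed-effects regression on donor age,
    compares groups with slope Z-tests and one-sided variance F-tests,
    runs per-context Wilcoxon tests with Bonferroni correction, tallies
    driver-gene mutations, and ships a fully seeded synthetic-cohort
    generator (toy reference genome plus matching VCFs with known ground
    truth) so the whole pipeline is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    nlme,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
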