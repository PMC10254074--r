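Package: haplomu
Title: De Novo Mutation-Rate Estimation from Haploid Pedigree Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating spontaneous mutation rates from
    parent-offspring pedigrees of haploid-diploid organisms such as brown
    algae. Provides callable-site accounting under strict and quorum
    coverage schemes, haploid de novo mutation candidate filtering for
    nucleotide, short-indel and structural variants, exact (Garwood)
    Poisson confidence intervals for rates, mutation-spectrum
    classification, spike-in false-negative simulation, coverage-window
    detection of whole-chromosome duplications, dosage-ratio analysis of
    duplicated chromosomes, and effective-population-size estimation from
    neutral diversity. Includes a synthetic pedigree generator with known
    ground truth (standing variants, somatic mosaics, mapping artifacts,
    chromosome duplications) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    methods,
    Biostrings,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
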