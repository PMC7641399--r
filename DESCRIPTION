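Package: hlapop
Title: HLA Population Variation Against a Neutral Marker Background
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing variation at the highly polymorphic HLA
    class I and II loci (HLA-A, -B, -C, -DRB1) in population samples, using
    a genome-wide microsatellite panel as a putatively neutral demographic
    control. Implements allele-name parsing at two-field resolution,
    heterozygosity and allele-count summaries, exact tests of
    Hardy-Weinberg proportions for multiallelic loci, the Ewens-Watterson
    homozygosity test with an exact conditional null, Tajima's D on
    sequence-recoded allele samples with a coalescent null, pairwise AMOVA
    F_ST and R_ST with an empirical Z_ST standardization against the
    microsatellite F_ST distribution, classification of alleles as endemic
    or large-frequency-difference (LFD) relative to a worldwide reference
    panel, EM estimation of two-locus haplotype frequencies, and
    allele-specific heterozygosity (ASH) summaries. A serial-founder
    cohort simulator with planted ground truth makes every stage testable
    without external data.
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
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
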