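Package: haplotract
Title: Experimentally Confirmed Haplotypes from Homozygosity Tracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines long, phasing-free reference haplotypes around a focal
    gene from diploid population genotype data. Individuals that are fully
    homozygous (or heterozygous at a single site) across the gene carry two
    unambiguous chromosomes there; each is extended in both directions to
    the nearest flanking heterozygous variant and catalogued as an
    experimentally confirmed haplotype, immune to the errors of statistical
    genotype phasing. Includes full-sequence materialisation against a
    reference window, deduplication with population breakdowns, length
    statistics, motif-based blood-group allele classification (Duffy/FY by
    default), IUPAC-aware comparison against external (e.g. archaic hominin)
    base profiles, and a seeded Hardy-Weinberg cohort simulator with
    exhaustive-search ground truth so the whole pipeline is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
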