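Package: contextmut
Title: Context-Dependent Mutagenesis Statistics from Population Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls ancestrally polarized biallelic mutation events from
    population-scale multiple alignments (MAF or aligned FASTA) using two
    agreeing outgroups, counts 1-4 bp word frequencies over complete
    alignments or conserved regions, and estimates context-dependent
    mutation statistics for all contiguous 2-4 bp mutation contexts:
    mutation bias (excess over the single-base rate), subcontext contrasts,
    and the minimal contrast (excess not explained by any subcontext).
    Also scores word over/under-representation against a maximal-order
    Markov expectation, summarizes single-nucleotide mutation spectra, and
    compares two species' context statistics. Includes a forward simulator
    that plants context-dependent rate multipliers in synthetic population
    alignments so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
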