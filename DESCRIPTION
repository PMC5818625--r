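Package: seedtox
Title: Seed-Mediated Off-Target Analysis for Chemically Modified siRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing microRNA-like off-target activity of
    chemically modified, GalNAc-conjugated siRNAs. Models modified
    oligonucleotide duplexes (2'-O-methyl, 2'-fluoro, phosphorothioate,
    glycol nucleic acid, 5'-caps) with design operations such as seed
    swapping, GNA placement and RISC-loading caps; scans 3'UTR sets for
    perfect complements of the antisense seed (nucleotides 2-8); classifies
    differential-expression tables and tests enrichment of seed matches
    among downregulated transcripts with a one-sided Fisher's exact test,
    including sense-strand and upregulated-direction controls; screens
    REVERSIR-style oligonucleotides for full complementarity to miRNAs; and
    simulates negative-binomial transcriptome responses with planted
    seed-dependent repression for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
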