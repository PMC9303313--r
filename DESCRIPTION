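Package: gapmertox
Title: Off-Target Screening and Hepatotoxicity Analysis for LNA Gapmer
    Antisense Oligonucleotides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and characterizing locked nucleic acid
    (LNA) gapmer antisense oligonucleotides (ASOs) with respect to
    hepatotoxicity risk. Implements transcriptome exclusion screening of
    candidate sequences, semi-global edit-distance ("d") off-target search
    and per-gene distance classification, TGC/TCC hepatotoxicity motif
    scanning, an off-target down-regulation index computed from expression
    ratio tables, serum AST/ALT hepatotoxicity calls, melting-temperature
    shift bookkeeping, and a seeded synthetic-data generator (transcriptome,
    expression, Tm and toxicity tables) so that every analysis stage is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
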