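Package: enzkinex
Title: Mining, Curation and Validation of Enzyme Kinetic Constants from Literature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A framework for turning kinetics tables scattered through the
    biochemical literature into a curated, sequence-mapped database of turnover
    numbers (kcat) and Michaelis constants (Km). Provides unit parsing and
    canonicalization with micro/milli glyph-ambiguity flagging, quality filters
    for hallucinated, repetitive and scientific-notation values, offline
    name-to-sequence and name-to-SMILES resolution with confidence tiers,
    assignment-based benchmarking against ground-truth curations
    (TP/FP/FN/Unresolved and off-by-10^k tallies), log-space concordance
    statistics with systematic-offset cluster detection, a synthetic glyph
    classifier, and a synthetic-corpus generator with controlled corruption
    injection so every stage is testable without a live extraction model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    stringr,
    stringi,
    readr,
    jsonlite,
    xml2,
    igraph,
    arrow,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    png,
    withr
Config/testthat/edition: 3
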