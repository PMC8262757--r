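Package: plasmidann
Title: Feature Annotation for Engineered Plasmids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates engineered plasmid sequences by homology search against
    nucleotide and protein feature libraries. Handles circular topology by
    sequence doubling with coordinate correction for origin-spanning matches,
    ranks hits with a length-identity-coverage priority score, resolves
    overlapping hits with a trimmed-core greedy filter, and flags incomplete
    feature fragments. Reads FASTA, GenBank, and raw sequence input; writes
    annotated GenBank, CSV, and BED output. Includes a deterministic synthetic
    fixture generator (toy feature libraries and composed plasmids with ground
    truth) so the whole pipeline is testable without external databases, plus
    adapters for external BLAST+ and Infernal tabular output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    utils,
    stats,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
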