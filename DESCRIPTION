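Package: refaudit
Title: Audit of DNA Barcode Reference Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality audit of aligned DNA barcode reference libraries (CO1 and
    similar markers). Reads an aligned FASTA plus specimen metadata, trims to
    the barcode window, screens reading frames for stop codons, profiles
    alignment sites, collapses haplotypes, computes uncorrected p-distances
    with pairwise deletion, summarises within- and between-cluster divergence
    with local barcoding-gap detection and nearest-neighbour identification,
    delimits molecular operational taxonomic units (MOTUs) by a single-linkage
    distance-threshold scan scored on the barcode gap, classifies congruence
    between morphological species names and barcode clusters (match, lump,
    split, both), and simulates barcode libraries with known ground truth so
    every stage is verifiable offline.
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
    tibble,
    tidyr,
    tidyselect,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
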