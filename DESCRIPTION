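Package: scarmux
Title: Multiplex SCAR Marker Design and In Silico PCR for DNA Barcode
    Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs species-specific SCAR (sequence-characterized amplified
    region) marker panels from species-labeled DNA barcode sequences and
    simulates the resulting multiplex PCR assay. From a multiple alignment it
    detects diagnostic substitution and indel sites fixed within one species
    and absent from all others, summarises intra- and inter-species Kimura
    2-parameter variability, builds neighbor-joining trees with bootstrap
    monophyly support, enumerates species-specific primer candidates anchored
    on diagnostic sites, assembles a multiplex panel whose amplicons form a
    gel-resolvable size ladder, and classifies query samples as authentic,
    adulterated or mixed from their virtual gel lanes. Includes a synthetic
    barcode-panel generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
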