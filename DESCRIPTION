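Package: goldenr
Title: Golden Gate Design and Assembly Simulation for Six-Module Yeast Expression Vectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and in-silico validation tools for a one-pot Golden Gate
    cloning system that assembles six position-specific functional modules
    (plasmid type, promoter, coding sequence, fusion/stop, terminator,
    selection marker) into a yeast expression vector. Provides tailed-primer
    design with position-specific BsaI overhangs, nearest-neighbor melting
    temperature with salt and single-mismatch corrections, a thirteen-metric
    primer quality battery, BsaI domestication by synonymous codon
    substitution, simulation of one-pot digestion/ligation assembly with
    overhang-compatibility checking, and design plus recombination modelling
    of single-copy targeted chromosomal integration using inverted homology
    arms. Ships a seeded synthetic module library mirroring the published
    collection structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    seqinr,
    stringi,
    tibble,
    withr,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
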