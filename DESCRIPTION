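Package: silicoplex
Title: In-Silico Multiplex PCR Species Identification for Sharpnose Sharks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing and simulating multiplex PCR species-identification
    assays on the nuclear ribosomal ITS2 locus, modelled on the triplex/nonaplex
    assays used to distinguish the seven sharpnose (Rhizoprionodon) shark species.
    Predicts amplicons from primer sets on template DNA under a mismatch/3'-anchor
    annealing policy, simulates agarose gel band patterns, calls species from band
    patterns, computes pairwise Tamura-Nei genetic distances, runs the upstream
    species-specific primer design pipeline (diagnostic-site discovery, candidate
    generation, specificity screening, amplicon size-ladder selection), and
    generates seeded synthetic ITS2-like sequence panels with controlled divergence
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    stringr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
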