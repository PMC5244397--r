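Package: antdev
Title: Developmental Transcriptome Analysis of the Drosophila Antenna
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-course RNA-seq analysis of the developing
    Drosophila antenna. Calibrates a per-stage negative-binomial background
    null on a negative-control gene family (non-antennal gustatory
    receptors) and calls olfactory receptors expressed or background at
    each developmental stage; reconstructs per-sensillum receptor onset
    order and Notch-fate tallies; clusters transcription-factor temporal
    profiles; and provides sample-level PCA and pairwise MA comparisons.
    Includes a negative-binomial count simulator that emulates the study
    design (four stages, two replicates, planted receptor onsets and
    transcription-factor cluster archetypes) so every stage of the
    pipeline is testable without the original raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    MASS,
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
    DESeq2,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
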