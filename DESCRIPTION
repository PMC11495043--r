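Package: magsecretome
Title: Predicted Secretome Profiling of Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrates per-protein subcellular-location and signal-peptide
    evidence for metagenome-assembled genomes (MAGs) into a compartment
    scheme (extracellular, outer-membrane, cell-wall, periplasmic,
    cytoplasmic-membrane, cytoplasmic, unknown, and unknown-with-signal-
    peptide), classifies secreted catabolic enzymes (CAZymes, nutrient
    peptidases, lipases, and iteratively expanded nucleases, RNases and
    nucleotidases), scans for CxxCH heme-binding motifs and multi-heme
    cytochromes, and aggregates results into per-MAG secreted-proteome
    niche profiles with outlier flagging, cohort statistics and orthogroup
    clustering. Ships a deterministic synthetic-cohort generator with
    planted ground truth so every stage is testable without external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
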