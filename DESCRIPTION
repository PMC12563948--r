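Package: cd44iso
Title: Classification of CD44 Protein Isoforms by Exon Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying protein isoforms of the human CD44 receptor
    against its 742-residue canonical sequence. Provides a deterministic global
    pairwise aligner with affine gap costs tuned so multi-exon splice-outs appear
    as single contiguous gap runs, parsing/rendering/normalisation/application of
    HGVS p.-level variant descriptors (substitution, deletion, insertion,
    deletion-insertion), matching of observed differences against a catalogue of
    exon-splice events, grouping of isoforms by exon composition, classification
    of alternative C-termini, scanning of genomic exon sequence for alternative
    AG/GT splice sites implied by microexon variants, and a seeded synthetic-data
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    tibble
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
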