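Package: gvreprog
Title: Quantifying Somatic Nuclear Reprogramming by Oocyte Germinal Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing transcriptional and chromatin-structural
    reprogramming of somatic nuclei transplanted into amphibian oocytes.
    The sequencing arm builds a two-species hybrid reference, assigns
    nascent (BrUTP-labelled) reads to species and gene by unique k-mer
    content, normalises counts to transcripts per million, classifies
    per-gene responses (activation, enhancement, repression) and identifies
    reprogramming-resistant genes. The imaging arm reimplements Huang fuzzy
    thresholding, iterative restricted-histogram multi-level Otsu chromatin
    density classification, recursive distance-map watershed segmentation of
    touching nuclei, HP1-alpha occupancy per density class and chromatin
    area comparisons. Synthetic generators for count data with known
    response classes and for two-channel nuclear images with known geometry
    make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
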