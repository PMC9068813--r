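Package: nelfkit
Title: Quantifying Enhancer-RNA-Driven NELF Release and Pol II Pausing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studying how enhancer RNAs (eRNAs) detach
    the negative elongation factor (NELF) from promoter-proximally paused
    RNA polymerase II. Provides strand-specific coverage containers and
    readers for BED/bedGraph, transcription start site calling from 5'-end
    read pileups with enhancer assignment, GRO-seq pausing-index
    computation and distribution comparison, eCLIP crosslink-site distance
    statistics with expression-normalised meta-profiles, quadratic
    ligand-depletion binding fits for apparent Kd estimation from gel
    densitometry, SHAPE-MaP reactivity normalisation and structure
    classification, and spectral-count aggregation for protein-RNA
    crosslinking mass spectrometry. A synthetic-data module generates
    inputs with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer,
    withr
Config/testthat/edition: 3
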