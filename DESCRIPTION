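Package: structatlas
Title: DNA Structural Atlases from Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes windowed DNA structural-property tracks (base-stacking
    energy, nucleosome position preference, intrinsic curvature, GC skew,
    AT content) and global direct/inverted repeat identity maps from a raw
    DNA sequence, and renders them as fixed-width multi-lane linear atlases
    at whole-locus and per-gene zoom scale. Tracks export to bedGraph, WIG
    and BED; gene annotations are read from GFF3 or GenBank flat files.
    Includes a synthetic-sequence generator for reproducible fixtures and a
    command-line interface.
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
    grDevices,
    jsonlite,
    methods,
    patchwork,
    purrr,
    ragg,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    BiocGenerics,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
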