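Package: mincell
Title: Integrative Characterization of a Near-Minimal Bacterium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the integrative characterization of small,
    wall-less bacteria (Mollicutes): inference of the most probable cell
    diameter, mass and volume from buoyant density and dry-mass measurements;
    doubling-time estimation from cell-count curves and colorimetric
    dilution assays; genome-wide transcription start site (TSS) calling from
    strand-specific 5'-RACE read-start tracks; Rho-independent terminator
    prediction and transcription-unit reconstruction on circular genomes;
    and conversion of RNA-seq (FPKM) and spectral-count (NSAF) expression
    into absolute molecules per cell using biomass composition. Includes a
    synthetic-data generator that plants promoters, terminators and operons
    in a miniature circular genome with a machine-readable truth object, so
    every stage of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
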