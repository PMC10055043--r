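Package: zonescape
Title: Dorsoventral Zonal Regulation of Olfactory Receptor Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for dorsoventral (zonal) regulation of mouse
    olfactory receptor (OR) genes: zonal OR annotation and genomic binning,
    single-cell OR repertoire analysis (QC, expressed-OR calling, zonal
    classification, knockout shift statistics), heterochromatin gene-body and
    metagene quantification from coverage tracks, bulk Hi-C trans-contact
    aggregation by zonal identity, single-cell 3D genome (.3dg) OR
    compartment statistics, and spatial transcriptomic zonal spot
    classification. Includes a seeded generative model of the opposing
    rheostats of polygenic OR transcription and dorsal-offset-dependent
    silencing, which emits all six input data kinds so the full pipeline runs
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    igraph,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
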