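Package: ulvabarcode
Title: Multi-Marker DNA Barcoding and Species Delimitation for Green-Tide Macroalgae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for molecular species identification of
    green-tide forming macroalgae (genus Ulva) from two-locus barcode data
    (chloroplast tufA and nuclear ITS). Provides Kimura 2-parameter distance
    summaries with complete or pairwise deletion, neighbor-joining and UPGMA
    trees with column-bootstrap supports, Automatic Barcode Gap Discovery
    (ABGD) partitioning with prior sweep and initial/recursive partition
    selection, single-threshold Generalized Mixed Yule-Coalescent (GMYC)
    delimitation on ultrametric trees, reference curation and tree-based
    specimen-to-species assignment with two-gene consensus and synonym
    handling, and a two-locus coalescent simulator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
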