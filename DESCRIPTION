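Package: bfuscan
Title: Detection and Classification of Electron-Bifurcating
    [FeFe]-Hydrogenase Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects gene clusters encoding electron-bifurcating group A3
    [FeFe]-hydrogenases (BfuABC and variants) in annotated bacterial
    genomes. Screens proteins for the three H-cluster binding motifs
    (P1/P2/P3) with a degenerate-pattern scanner, extracts the five-gene
    neighborhood around each catalytic-subunit anchor, assigns subunit
    roles from declared domain architectures, filters clusters for an
    intact bifurcating BfuB/BfuC core, classifies retained clusters into
    the five organizational sub-types (BfuABDC, BfuABC, BfuCAB, BfuABCT,
    BfuTABC), applies iron-sulfur/flavin completeness rules to predict
    bifurcation capability, and cross-checks the organizational sub-typing
    with an alignment-free neighbor-joining phylogeny of concatenated
    A+B+C subunits. Ships a seeded synthetic-genome generator with a
    ground-truth table so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
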