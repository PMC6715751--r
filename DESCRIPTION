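Package: ScreenMux
Title: Analysis of Multiplexed 2D/3D Anticancer RNAi Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of well-based siRNA screening campaigns with
    multiplexed readouts (2D cell count, 2D viability, 3D sphere count):
    per-plate normalization against negative controls, Z'-factor quality
    control, replicate-level hit calling with one-sided t-tests and
    fold-change thresholds, cross-screen classification of hits into 2D-only,
    3D-only, common and selective groups, dissection of total viability into
    per-cell viability to separate susceptibility from resistance responses,
    GO-annotation Tanimoto similarity networks, and gene-set enrichment
    (hypergeometric over-representation and a GSEA-style running-sum
    statistic). Includes a plate-structured synthetic screen generator with
    planted per-gene effects so every stage is testable against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), fgsea, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
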