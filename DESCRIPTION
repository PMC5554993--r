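Package: dimscreen
Title: Systems-Level Screening of Drug-Induced Myopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reusable pipeline for systems-level analysis of drug-induced
    myopathy and similar index adverse events. Screens a binary
    drug-by-side-effect matrix for co-occurring adverse events with
    Fisher's exact test, Benjamini-Hochberg correction and a compound
    confusion-matrix criterion (MCC, sensitivity, true-positive floor);
    tests whether index drugs are chemically more self-similar than
    random drug sets by Jaccard fingerprint similarity with a
    randomized-negative permutation test; ranks protein targets by
    frequency among index drugs and extracts the confidence-filtered
    protein-protein interaction subnetwork among the top targets; merges
    per-cell-line ranked gene lists into prototype ranked lists by Borda
    aggregation, extracts top/bottom signature genes, and runs
    hypergeometric gene-set enrichment. Includes a synthetic cohort
    generator with planted ground truth so the whole pipeline is testable
    without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
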