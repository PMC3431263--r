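Package: hiddenpath
Title: Topological Hidden-Node Discovery and Pathway Concordance for
    Multi-Omic Cell-Line Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates transcriptomic and glycoproteomic differential
    profiles from paired metastatic/non-metastatic cell-line models over a
    global protein interaction network. Provides threshold-based
    differential selection, label-free spectral-count quantification with
    Fisher exact testing and step-up correction, a shortest-path
    topological significance score with a degree-matched resampling null
    that flags "hidden" nodes absent from the direct differential sets,
    hypergeometric pathway over-representation with
    Benjamini-Hochberg FDR, cross-model concordance statistics,
    random-gene-set FDR calibration, and a reverse phase protein array
    (RPPA) pathway enrichment test. A synthetic scenario generator with
    planted ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
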