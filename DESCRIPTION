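Package: dropletcall
Title: Cluster-Based Cell Calling for Droplet Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("dropletcall", "developers", email = "dropletcall@example.org",
           role = c("aut", "cre"))
Description: Distinguishes real cells from ambient-RNA background barcodes in
    droplet-based single-cell RNA-seq UMI count matrices. Implements a
    cluster-based Monte-Carlo test that groups similar low-count barcodes
    before testing them against a Good-Turing smoothed ambient profile,
    together with the classical individual-barcode Dirichlet-multinomial
    test it extends, knee/inflection detection on barcode-rank curves,
    a simulation framework with per-barcode truth labels for power and
    false-discovery-rate evaluation, and command-line entry points.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
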