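Package: tfmirnet
Title: Integrated Transcription Factor and microRNA Regulatory Network
    Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers integrated transcription factor (TF) and microRNA
    regulatory networks from expression time-courses, ChIP-Seq peak
    intervals, position weight matrix (PWM) promoter scans, and consensus
    miRNA target lists. Includes a feature-voting predictor of pri-miRNA
    transcription start sites, a phylogenetically weighted TF binding
    score with permutation p-values, master-regulator enrichment tests
    (rank-based and hypergeometric), stepwise network assembly with
    evidence provenance, and coherent/incoherent feedforward and feedback
    motif classification. Ships a synthetic-scenario generator with
    planted ground truth so the full pipeline can be exercised and
    benchmarked without external genome-scale resources.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph,
    yaml,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
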