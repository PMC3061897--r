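Package: metaregnet
Title: Meta-Regulation Networks of Transcription Factors, microRNAs and
    Target Genes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and analyses multi-level gene-regulation networks that
    combine transcriptional (TF to gene, TF to miRNA) and
    post-transcriptional (miRNA to gene) regulation. Provides
    position-weight-matrix scanning of upstream sequences with relative
    scores in [0,1] and empirical p-value calibration against a reference
    sequence, unification of heterogeneous miRNA-target prediction scores
    onto a common uniform 0-1 scale, Fisher exact ranking of candidate
    regulators with expression-based contextual filtering, assembly of
    TF/miRNA/gene regulation graphs, exhaustive extraction of feedback and
    feedforward loop motifs, seeded synthetic benchmark generation with
    planted ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
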