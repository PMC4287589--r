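Package: mscportrait
Title: Genome-Scale Expression Portrait of Mesenchymal Stromal Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterise the transcriptome of mesenchymal
    stromal/stem cells (MSCs) from bulk RNA-seq: calling an expression
    footprint from FPKM matrices by a quantile or fixed log2 threshold,
    hypergeometric gene-set enrichment, a consensus transcription-factor
    binding-site over-representation engine with random-reference-set
    penalties that nominates meta-regulator transcription factors,
    Illumina 450k Beta-value methylation profiling of TF genes,
    a two-engine differential-expression consensus, and assembly of an
    evidence-weighted TF-TF protein-interaction network. A seeded
    synthetic-data module generates every input with planted ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    fgsea,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
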