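Package: scregulon
Title: Cell-Type-Specific Regulon Inference from Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers cell-type-specific regulons (CTSRs) from a gene-by-cell
    expression matrix. Co-expressed gene modules are detected by qualitative
    biclustering, assigned to cell types by hypergeometric enrichment of their
    cell sets, linked to transcription factors by scanning promoter sequences
    with known position weight matrices, and scored for cell-type specificity
    with rank-based activity scores, a divergence-based specificity score, and
    a bootstrap empirical null. Includes readers for dense and 10x-style
    sparse expression matrices, cell labels, MEME-format motif libraries and
    GTF/BED gene annotation, a synthetic-data generator with planted ground
    truth, clustering-agreement indexes and Wilcoxon marker-gene detection
    for evaluation, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
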