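Package: rsmtargets
Title: RAP-Seq Target Identification for CsrA/Rsm-Family RNA-Binding Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for mapping the in-vivo RNA regulons of
    CsrA/Rsm-family post-transcriptional regulators from affinity-purification
    sequencing (RAP-Seq) tag data. Implements a transparent MACS-style
    enrichment peak caller with Poisson local-background scoring and empirical
    sample-swap FDR, technical-replicate consensus filtering, confidence
    interval based fold-enrichment and p-value score cut-off selection,
    peak-to-RNA annotation with summit-based disambiguation of divergent gene
    pairs, multi-protein regulon comparison, and a synthetic-data generator
    with planted ground truth that emulates the replicate structure of a
    three-protein pulldown study, so the whole cascade runs and is scored
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
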