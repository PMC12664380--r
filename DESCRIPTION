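Package: mepdiverge
Title: Transcriptome and Chromatin-Accessibility Divergence at a
    Hematopoietic Lineage Bifurcation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of transcriptome and chromatin-accessibility divergence
    from a bipotential megakaryocyte-erythroid progenitor (MEP) into its two
    daughter lineages (megakaryocyte, erythroblast). Provides FPKM
    log-transformation and expressed/silent thresholding, partitioning of
    genes by lineage sharing, nine-category differential-expression consensus
    classification (pairwise tests intersected with k-means pattern
    clustering), transcription-factor occupancy enrichment over gene
    neighborhoods, and a candidate cis-regulatory element (cCRE) signal-state
    discordance analysis that discretizes ATAC-seq signals into
    high/medium/low states, tabulates the 27 cross-cell-type categories and
    tests precocious-actuation and RNA-retention hypotheses by Fisher
    odds-ratio enrichment with Woolf confidence intervals. A seeded
    multi-omic simulator with known ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
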