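Package: orthotss
Title: Comparative dRNA-Seq Analysis of Orthologous Transcription Start Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers, classifies and cross-species matches transcription start
    sites (TSSs) from differential RNA-seq (dRNA-seq) data for pairs of related
    bacterial genomes profiled under two phenotypic conditions. Provides read
    clipping and alignment filtering, normalized strand-specific 5'-end
    coverage, a step-height/TEX-enrichment TSS caller with chain-linkage
    clustering, positional TSS classification (genic, antisense, internal,
    intergenic), reciprocal-best-hit single-copy ortholog detection with
    protein, codon and 5'-UTR alignment coordinate maps, positional TSS
    orthology under an alignment-column distance criterion, condition
    fold-change consistency screening, and conservation statistics (Fisher's
    exact test with FDR, chi-square test for linear trend, Wilcoxon
    signed-rank). Includes a two-species synthetic-data generator with planted
    TSS truth so that the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    rtracklayer,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
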