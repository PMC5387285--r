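Package: batchbias
Title: Detection and Characterization of Batch-Biased Somatic Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies somatic variant calls whose carriers are
    significantly concentrated in non-biological sample batches (plate,
    tissue source site, sequencing center) in MAF-format tumor cohorts
    with TCGA-style barcodes, using Fisher's exact test on per-variant
    contingency tables with Benjamini-Hochberg multiplicity control and
    representative-batch collapsing. Characterizes flagged variants by
    mutation spectrum, flanking GC content, homopolymer-run context,
    gene-region and splice-site enrichment, position frequency matrices
    and k-mer motif enrichment, and by their effect on sample clustering
    in Neighbor-Joining trees of binary mutation profiles. Includes a
    fully deterministic synthetic-cohort generator (reference genome,
    gene models, barcoded samples, background and planted batch-biased
    variants with ground truth) so every stage is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
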