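Package: fusionkd
Title: Fusion-Aware Knockdown Transcriptomics and Drug-Screen Analytics
Version: 0.1.0
Authors@R: person("OV054", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Re-usable pipeline for fusion-driven sarcoma knockdown studies:
    construction of an edited ("split") reference transcriptome in which each
    fusion partner gene is replaced by 5' and 3' half-transcripts cut at the
    breakpoint exon, exact k-mer assignment of paired-end reads to the edited
    reference, RPKM matrices, junction-panel counting of +KTS/-KTS fusion
    isoform reads, breakpoint detection from junction-spanning reads, a
    two-shRNA intersection rule for calling fusion target genes, gene-set
    Z-score construction and overlap reports, and medium-throughput drug
    screen analytics (DMSO normalization, log-dose AUC, cross-model AUC
    Z-scores, four-parameter logistic IC50 fits, plasma-concentration hit
    selection). Includes seeded synthetic-data generators with full truth
    tables for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
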