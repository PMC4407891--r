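Package: apakit
Title: Alternative Polyadenylation Analysis for 3' End Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies alternative cleavage and polyadenylation (APA) from
    3' end sequencing read counts. Filters poly(A) site-supporting (PASS)
    reads, clusters cleavage positions into poly(A) sites, classifies sites
    against a gene annotation (tandem 3'UTR sites, intronic sites, upstream
    antisense and TSS-proximal sense transcripts), and tests differential
    isoform usage between two samples with a bootstrap randomization test on
    the relative expression difference (RED) statistic, including a
    depth-matched bootstrap/permutation normalization for global counts of
    regulated events. Also provides k-mer enrichment around cleavage sites,
    nucleotide frequency profiles, intron-position bias summaries, and a
    seeded synthetic data generator that emulates 3' end sequencing reads
    with planted usage shifts and sequence motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    fgsea,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
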