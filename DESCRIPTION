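Package: curupira
Title: Discovery and Characterization of piRNA Clusters on Supernumerary
    (B) Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering PIWI-interacting RNA
    (piRNA) clusters from gonadal small-RNA sequencing and locating them on
    a supernumerary (B) chromosome. Small-RNA reads are length-filtered
    (24-35 nt), collapsed to unique sequence tags, and placed exactly on a
    reference genome with fractional multi-mapper weighting; clusters are
    called from maximal hit runs under the canonical acceptance criteria
    (>= 0.75 weighted fraction of reads with 1U or 10A, >= 0.75 with
    typical piRNA length, >= 1000 bp span) and classified as mono- or
    bidirectional. B-resident loci are flagged by normalized B+/B- genomic
    read-depth ratios (> 2) together with B-specific SNP calls; the
    transposable-element content of loci is profiled and dated with Kimura
    two-parameter divergence landscapes; gene dosage and expression are
    quantified from qPCR Cq tables by the delta-delta-Cq method with a
    permutation test for group effects. A fully seeded synthetic-data
    generator (genomes, planted clusters, TE copies, sRNA libraries, B-/B+
    WGS read sets) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
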