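Package: m6aquant
Title: Quantification and Comparative Analysis of m6A-seq (MeRIP-seq) Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis of transcriptome-wide N6-methyladenosine
    (m6A) sequencing experiments with paired mRNA-seq controls. Implements
    covered-length normalized m6A quantification (MFPKM), chi-square based
    categorization of methylation extent relative to transcript level,
    NFPKM-based differential methylation between organs or tissues with
    Benjamini-Hochberg FDR control, 60-bin metagene topology profiles with
    Type 1/Type 2 classification, RRACH consensus motif analysis over top
    peaks, and qRT-PCR validation arithmetic. Ships a seeded synthetic-data
    generator (genome, transcript models, m6A-seq/mRNA-seq/input fragment
    libraries with known ground truth) so every pipeline stage is testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
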