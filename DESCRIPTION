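Package: magscreen
Title: Barcoded Transposon Screens with Magnetic-Column Selection
Version: 0.1.0
Authors@R: person("Screen", "Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for random barcoded transposon (RB-TnSeq)
    mutant libraries subjected to physical enrichment screens, modeled on
    magnetic-column selection of magnetotactic bacteria. Maps barcoded
    insertions to a reference genome, computes library quality statistics,
    calls essential genes from insertion density with a Poisson
    minimum-length threshold, counts barcodes per sample from BarSeq reads,
    and computes weighted gene-level magnetic column scores (MCS) normalized
    against precolumn abundance. Includes a forward simulator of the whole
    screen (genome, insertion pool, column partition, FASTQ emission) with
    ground-truth tables, and normality-gated comparison tests for
    magnetosome morphometry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
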