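Package: tetrasnp
Title: Homoeolog SNP Classification, Phasing and Expression Bias in
    Allotetraploid Wheat Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for allotetraploid (AABB) transcriptome
    analysis: per-position variant calling from read alignments with
    quality-window and count filters, classification of multi-variety
    genotype matrices into simple, hemi-, inter-homoeolog, multi-genotype
    and misassembly SNP categories, read-backed phase-block reconstruction
    by Minimum Error Correction with A/B subgenome assignment, editing of
    homoeolog-specific transcript sequences, double-reference
    homoeolog-specific read counting, negative-binomial homoeolog
    differential-expression testing, and assembly-completeness metrics.
    Includes a synthetic allotetraploid data generator providing ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    IRanges,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
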