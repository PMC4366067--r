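Package: ploidosage
Title: Dosage-Response Analysis of Allopolyploid Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative comparison of allotriploid and allodiploid
    expression profiles from per-library abundance tables. Provides
    fold-change (ratio) profiling with chi-square tests on the balance of
    lower versus higher expressed transcripts, partitioning of similarly
    expressed genes into dosage-response classes (compensated, dosage
    sensitive, repressed, overexpressed), differential-expression calling
    with a two-library exact binomial test and a dependent-test
    (Benjamini-Yekutieli) false discovery rate correction, mid-parent
    additivity assessment for hybrids, and relative transcriptome-size
    estimation that couples genome-normalized qPCR (Livak 2^-ddCq with
    genomic-DNA reference normalization) with per-transcriptome RNA-seq
    abundances. A synthetic-data generator emulates four-genomotype
    expression tables and qPCR plates with known ground truth so every
    pipeline stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
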