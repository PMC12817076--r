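Package: annoclass
Title: Classification and Accuracy Assessment of Eukaryotic Gene Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coordinate-based assessment of predicted gene annotations against
    a reference. Classifies every reference gene locus as exact, inexact,
    missing, merged, or fragmented; tallies matched, missing, and
    false-positive transcripts, coding exons (by 5', internal, 3', and
    single-exon position), and introns; computes sensitivity, precision, and
    F1 at nucleotide, exon, intron, and transcript stringencies; compares
    per-gene F1 distributions with a variance-weighted two-sample ECDF
    permutation test; extends curated "gold standard" reference gene sets
    with genes that BUSCO reports as complete, including the validating
    two-proportion z-test; partitions reference genes by the subset of
    prediction pipelines that recover them; and generates synthetic
    reference/prediction annotation pairs with known injected defects for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
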