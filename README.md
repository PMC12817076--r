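# annoclass

Coordinate-based assessment of predicted gene annotations against a
reference, for people who build or benchmark eukaryotic genome annotation
pipelines.

Accuracy summaries alone hide *how* an automated annotation goes wrong.
`annoclass` classifies every reference gene locus into one of five
outcomes from the intersection of genomic feature coordinates:

| outcome | meaning |
|---|---|
| **exact** | one prediction, identical 5′/3′ span boundaries |
| **inexact** | one prediction, overlapping but shifted boundaries |
| **missing** | no prediction matched (a false-negative locus) |
| **merged** | one prediction spans ≥ 2 reference genes, each covered by > 50% of its length (intergenic region mistaken for an intron) |
| **fragmented** | ≥ 2 disjoint predictions each lie (≥ 50% of their own span) inside one reference gene (intron mistaken for an intergenic region) |

Around that core it provides:

* transcript / coding-exon / intron tallies of matched, missing, and
  false-positive features, pairing transcripts by the maximum total
  nucleotide overlap of their CDS footprints (an exact assignment
  optimum), with exons broken down by 5′ / internal / 3′ / single position;
* accuracy statistics at four stringencies — Sn = TP/(TP+FN),
  Pr = TP/(TP+FP), F1 = 2·Sn·Pr/(Sn+Pr) — and per-gene F1 scores for ECDF
  comparison;
* a variance-weighted two-sample ECDF permutation test
  (DTS = Σ |F̂−Ĝ| Δx / √(Ĥ(1−Ĥ))) and the pooled two-proportion z-test;
* "gold standard" reference-set extension: curated gene ids plus uncurated
  genes whose proteins BUSCO reports complete, with the validating
  fragmented-to-complete z-test;
* a multi-pipeline agreement partition (genes per 1000 recovered by each
  subset of pipelines), 2-of-3 evidence-concordance gene selection, and a
  synthetic annotation generator that injects all five defect classes with
  known truth labels.

Everything takes and returns tibbles, composes with the pipe, and has
`tidy()` / `glance()` / `autoplot()` methods where a fitted-object view
makes sense.

## Worked example

Two small synthetic GFF3 files (12 reference genes; predictions with
known injected defects) ship with the package:

```r
library(annoclass)

ref  <- read_gff3(system.file("extdata", "synthetic_reference.gff3",
                              package = "annoclass"))
pred <- read_gff3(system.file("extdata", "synthetic_predictions.gff3",
                              package = "annoclass"))
report <- evaluate_report(pred, ref)
report
#> <annotation_report> synthetic_predictions.gff3 vs synthetic_reference.gff3
#>   12 reference gene(s), 10 prediction gene(s), 0 unassigned
#>
#> Gene outcomes:
#> # A tibble: 5 × 3
#>   outcome        n fraction
#>   <fct>      <int>    <dbl>
#> 1 exact          4   0.333
#> 2 inexact        3   0.25
#> 3 missing        2   0.167
#> 4 merged         2   0.167
#> 5 fragmented     1   0.0833
#>
#> Accuracy:
#> # A tibble: 4 × 7
#>   level         TP    FP    FN    Sn    Pr    F1
#>   <chr>      <int> <int> <int> <dbl> <dbl> <dbl>
#> 1 nucleotide 15146   229  3892 0.796 0.985 0.880
#> 2 exon          44     6    16 0.733 0.88  0.8
#> 3 intron        40     1     9 0.816 0.976 0.889
#> 4 transcript     5     6     8 0.385 0.455 0.417
```

Reading the numbers: of 12 reference genes, 4 were recovered with exact
boundaries and 3 with shifted boundaries; 2 were absent from the
predictions, one adjacent pair was fused into a single model, and one gene
was split in two. 79.6% of reference coding bases are covered by predicted
coding bases (Sn) and 98.5% of predicted coding bases are correct (Pr);
transcript-level F1 is much lower because it demands every segment
boundary of a chain to be identical.

Comparing per-gene F1 distributions and extending a reference set:

```r
f1 <- report$per_gene_f1
dts_test(f1$F1[1:6], f1$F1[7:12], n_permutations = 999, seed = 1)
#> two-sample ECDF permutation test (DTS statistic)
#> DTS = 0.617584, p = 0.449 (999 permutations, n = 6 vs 6)

recs    <- read_busco_table(system.file("extdata",
             "synthetic_busco_full_table.tsv", package = "annoclass"))
curated <- read_id_list(system.file("extdata",
             "synthetic_curated_ids.txt", package = "annoclass"))
glance(build_gold_standard(recs, curated, organism_label = "example"))
#> # A tibble: 1 × 5
#>   organism n_curated n_busco_added n_total percent_increase
#>   <chr>        <int>         <int>   <int>            <dbl>
#> 1 example          4             7      11              175
```

The DTS test finds no significant difference between the two (here
arbitrary) halves of the per-gene F1 sample; the gold standard grows from
4 curated genes to 11 by adding 7 uncurated genes whose proteins the
BUSCO-style assessment reports complete.

A thin command-line front end wraps the same functions
(`inst/cli/annoclass`): subcommands `simulate`, `evaluate`, `agree`,
`concordance`, `extend-refset`, `dts-test`.

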