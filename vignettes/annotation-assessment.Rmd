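---
title: "Assessing gene annotations by coordinate-based defect classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing gene annotations by coordinate-based defect classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annoclass)
```

## The problem

Automated annotation pipelines for eukaryotic genomes produce gene models
that can be wrong in qualitatively different ways: a gene may be missed
entirely, two neighbouring genes may be fused into one model when an
intergenic region is mistaken for an intron, or a single gene may be split
into several models when an intron is mistaken for an intergenic region.
Classical sensitivity/precision summaries hide these failure modes.
`annoclass` classifies every reference gene locus into one of five
outcomes — **exact**, **inexact**, **missing**, **merged**, **fragmented** —
purely from the intersection of genomic feature coordinates, and surrounds
that classification with feature-level tallies, accuracy statistics, ECDF
comparison of per-gene F1 scores, BUSCO-based reference-set extension, and
multi-pipeline agreement partitioning.

## The annotation model

An annotation is a tibble of CDS segments (`contig`, `strand`, `gene_id`,
`transcript_id`, `start`, `end`; 1-based inclusive, as in GFF3). Exons are
always *coding* exons: UTRs are never modelled, and a gene's span runs from
its smallest CDS start to its largest CDS end. Introns are derived, not
read: the gap between consecutive CDS segments of one transcript, provided
the gap is at least 1 nt (directly adjacent segments imply no splice
junction and produce no intron). Coding exons carry a position class —
initial (5′-most in transcription direction), internal, terminal, or
single — so that boundary-exon failures can be reported separately from
internal-exon failures.

Unstranded features are excluded from all matching (the classifier is
strand-aware); strict parsing rejects them, lenient parsing skips them with
a warning. CDS phase is parsed but never used: the classification is purely
coordinate-based.

## The gene outcome classifier

For prediction and reference sets on a shared coordinate system,
`classify_genes()` proceeds in a fixed order, each step *consuming* its
participants so that the five outcomes partition the reference set:

1. **Merged** — a prediction whose span covers two or more reference genes,
   each by *strictly more than* `merged_ref_coverage` (default 0.5) of the
   reference's span length.
2. **Fragmented** — a remaining reference overlapped by two or more
   remaining predictions, each placing at least `fragment_pred_coverage`
   (default 0.5, non-strict) of *its own* span inside the reference span,
   with pairwise overlap between fragments at most
   `fragment_mutual_overlap_max` (default 0, i.e. disjoint) of the shorter
   fragment.
3. **One-to-one matching** — remaining overlapping prediction/reference
   pairs are resolved by maximum-weight assignment on span overlap
   (an exact optimum, not a greedy pass). A pair with identical span
   boundaries is **exact**; otherwise **inexact**.
4. Leftover references are **missing**; leftover predictions are reported
   under a separate `unassigned_prediction` outcome. Keeping unmatched
   predictions out of the reference partition lets downstream reports
   either ignore them or count them as gene-level false positives,
   whichever presentation is wanted.

Design choices worth making explicit:

* **Precedence.** The outcome classes are individually defined but their
  interaction is open; resolving merged before fragmented before
  one-to-one, with consumption, is what guarantees a clean partition. The
  order puts the multi-gene defect first because a merged prediction would
  otherwise soak up one of its references as an inexact match.
* **Span versus footprint.** The merged/fragmented coverage tests use gene
  *spans* (CDS extrema). Using CDS footprints instead is a plausible
  variant; spans were chosen because the defects being detected are
  boundary-scale events.
* **Fragment denominator.** "Each fragment overlaps by at least 50%" is
  read against the fragment's *own* span: at least half of each predicted
  fragment must lie inside the reference. This makes the test invariant to
  how much of the reference the fragments jointly cover.
* **Separation of fragments.** "Separate portions" is enforced as a cap on
  pairwise fragment overlap (default: disjoint). When more than two
  candidate fragments conflict, a maximal subset is retained greedily in
  genomic order — deterministic and order-stable.
* **Strand.** Opposite-strand overlap is never a match; coding orientation
  defines the gene.

Raising `merged_ref_coverage` can only shrink the merged set, and raising
`fragment_pred_coverage` can only shrink the fragmented set; both
monotonicity properties are asserted in the test suite.

## Transcript, exon and intron matching

Within a classified locus (pooling all genes of a merged or fragmented
group), prediction and reference transcripts are paired one-to-one so that
the summed nucleotide overlap of their CDS *footprints* (segment unions —
long introns cannot fabricate overlap) is maximal. The optimum is computed
exactly by dynamic programming over subsets of the smaller side; gene loci
never hold more than a handful of isoforms, and a hard error is raised
beyond 16 features per side. Zero-overlap pairs are never created.
Unpaired reference transcripts are missing; unpaired predictions are false
positives.

Ties between equally optimal assignments are broken deterministically:
references are processed in genomic start order and each takes the
earliest-starting prediction compatible with the optimum.

Within each transcript pair, exons and introns are matched by the same
maximum-overlap assignment (for collinear, non-overlapping features this
reduces to matching in genomic order — an equivalence the tests assert).
Every tally satisfies, by construction,
`matched + missing = reference feature count` and
`matched + false_positive = prediction feature count`; exact-coordinate
match counts are reported alongside for the strict stringency.

## Accuracy statistics

`confusion_counts()` computes TP/FP/FN at four stringencies: per-base CDS
membership on each (contig, strand) at the *nucleotide* level; exact
coordinate identity for *exons* and *introns* (features deduplicated
across isoforms); and exact CDS-chain identity for *transcripts*. `Sn =
TP/(TP+FN)`, `Pr = TP/(TP+FP)`, `F1` their harmonic mean, with the 0/0 → 0
convention so that `F1 = 0` exactly when nothing is recovered.

Per-gene F1 scores (the ECDF material) are computed at nucleotide
stringency: each reference gene's CDS footprint against the pooled
footprint of the predictions classified with it, 0 for missing genes.
Whole-set statistics in `evaluate_report()` are computed over the
predictions that were classified to some reference; `unassigned_prediction`
genes are excluded there (and reported separately), which is what makes
evaluation restricted to a gold-standard subset exactly equal to
evaluation against a pre-filtered reference.

## Two-sample ECDF comparison (DTS) and the z-test

For samples of sizes $n$ and $m$ with ECDFs $\hat F$, $\hat G$ and pooled
ECDF $\hat H$ over the pooled order statistics $x_{(1)} \le \dots \le
x_{(n+m)}$:

$$\mathrm{DTS} = \sum_{k=1}^{n+m-1}
  \frac{|\hat F(x_{(k)}) - \hat G(x_{(k)})|\,(x_{(k+1)} - x_{(k)})}
       {\sqrt{\hat H(x_{(k)})\,(1 - \hat H(x_{(k)}))}}$$

a variance-weighted Wasserstein-like distance that up-weights tail
discrepancies. Terms with $\hat H \in \{0, 1\}$ or tied consecutive values
contribute nothing. The statistic is symmetric, zero iff the multisets
coincide, and scales linearly under a joint positive rescaling. Any
alternative constant normalisation of the weight would cancel in the
permutation test, which is why the *test*, not the raw statistic, is the
interface contract. Significance comes from randomly re-partitioning the
pooled values into groups of the original sizes; the p-value uses the
add-one estimator $(1 + \#\{\text{permuted} \ge \text{observed}\}) /
(B + 1)$, so $p = 0$ is unattainable and the test is valid at finite $B$.
A seed is mandatory — identical seeds give identical p-values. Calibration
is checked empirically: over 500 null trials ($n = m = 30$, $B = 500$,
$\alpha = 0.05$) the rejection rate must fall inside the exact binomial
99% interval around 0.05.

The two-proportion z-test (`two_proportion_ztest()`) uses the pooled
variance and no continuity correction, two-sided; a degenerate pooled
proportion (0 or 1) is defined as $z = 0$, $p = 1$. It backs
`fragmented_complete_ztest()`, which compares
`Fragmented / (Fragmented + complete-class)` rates between curated and
uncurated gene groups — "fragmented-to-complete" is read as a proportion,
not an odds ratio.

## BUSCO-based gold-standard extension

`build_gold_standard()` unions a curated gene-id list with the ids of
uncurated genes whose proteins BUSCO reports in a complete-class status.
The complete class defaults to {Complete, Duplicated}: a duplicated
protein is individually complete; a strict Complete-only mode is
available. Curated genes are retained regardless of their own BUSCO
status — curation is the higher evidence tier — and one complete-class
record suffices when several BUSCO entries point at the same gene.
`Missing` records name no gene and belong to neither curation group. The
summary reports the percent increase `100·|added|/|curated|` (absent when
no curated genes exist).

## The synthetic annotation generator

`generate_reference()` emulates a compact eukaryotic genome: genes of 1–8
coding exons of 100–500 nt separated by introns of 60–300 nt, placed
left-to-right with intergenic gaps drawn from [200, 600] nt, strands
i.i.d. at 0.5, and an exon-skipping isoform on 20% of genes with at least
three exons. These defaults are one fixed choice of realistic scales, not
tuning knobs; genes never overlap and always respect the minimum gap,
which is what makes injected defect labels unambiguous.

`inject_defects()` perturbs a reference into a prediction set with truth
labels, assigning defects to disjoint gene subsets in the fixed order
merged → fragmented → missing → inexact (remainder exact):

* *merged* — two adjacent same-strand genes replaced by one prediction
  chaining both segment sets (each reference covered at 1.0 > 0.5, the
  intergenic gap becoming an intron, mirroring the defect's real
  mechanism);
* *fragmented* — a multi-exon gene split at an intron into two disjoint
  predictions fully inside the reference span (self-coverage 1.0 ≥ 0.5);
* *inexact* — both span boundaries shifted by at least 1 nt and at most
  `jitter_magnitude` (default 0.1) of the gene length, never crossing the
  midpoint of a flanking intergenic gap and never hollowing out a terminal
  exon, so a jittered gene can never trip the merged or fragmented
  thresholds;
* transcript-level noise: spurious isoforms (structurally wrong copies)
  and dropped isoforms, at configurable rates.

The central closure property — `classify_genes()` recovers every injected
label — is exercised on 1000-gene genomes (five 1.2-Mb contigs; 100 merged
pairs, 100 fragmented, 100 missing, 200 inexact, 400 exact) across 51
seeds in the test suite, with zero tolerated failures.

What the generator does **not** emulate: nucleotide sequence (no FASTA),
overlapping or nested genes, trans-splicing, UTR structure, alternative
splicing beyond single-exon skipping, and boundary-ambiguous defects whose
coverage sits exactly at a threshold. Passing the closure test therefore
shows the classifier implements its stated rules exactly; it does not show
that real pipeline errors are always as cleanly separated as the injected
ones. Threshold-boundary behaviour is instead pinned by small hand-built
fixtures (coverage exactly 0.5, touching fragments).

## Numerical and degenerate-input conventions

* Intervals are 1-based inclusive everywhere (GFF3 convention); overlap
  arithmetic is closed-form on integers, so there are no floating
  tolerances in the classifier itself.
* Coverage thresholds: merged is strict (`>`), fragmented non-strict
  (`≥`), mirroring "more than half" versus "at least 50%".
* 0/0 → 0 for Sn, Pr, F1; empty feature levels tally zeros rather than
  erroring.
* The DTS permutation seed is required, and the generator/injector accept
  explicit seeds; all seeded paths save and restore the caller's RNG
  state.
* `dts_test()` demands at least 2 values per sample; `dts_statistic()`
  only non-emptiness.
* Assignment groups beyond 16 × 16 raise an error rather than silently
  degrading to a heuristic.

## Problem sizes used for validation

The suite validates the assignment optimum against exhaustive enumeration
on 500 random groups of up to 6 transcripts per side, nucleotide confusion
counts against literal per-base bitmaps on 200 random ≤ 10-kb instances,
the z-test against an independent high-precision evaluation on 1000 random
count configurations (1e-10), and DTS calibration on 500 null trials.
These sizes were chosen as the smallest giving the properties no room to
hide, while keeping a full test run in minutes on one CPU.

## Known limitations

* Gene-level "exact" refers to span boundaries only; internal-structure
  exactness is reported at the exon/intron/transcript levels instead.
* The fragmented rule's subset selection is greedy-maximal when more than
  two candidate fragments mutually conflict; a different maximal subset
  could in principle exist.
* A merged prediction's leftover reference (covered ≤ 50%) remains in the
  pool and may still match another prediction — deliberate, but one of
  several defensible readings.
* Whether per-gene F1 ECDFs should use nucleotide or exon stringency is
  genuinely open; nucleotide stringency is computed and so labelled.
* GTF and other attribute dialects, UTR accuracy, phase validation and
  isoform quantification are out of scope.
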