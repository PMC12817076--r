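# Synthetic annotation generator: reference gene sets with realistic
# exon/intron structure on linear contigs, and prediction sets derived
# from them by injecting the five gene-level outcome classes plus
# transcript-level noise, with full truth labels. This is what makes the
# classifier and the statistics testable without any genome downloads.

#' Parameters for the synthetic reference generator
#'
#' Defaults emulate a compact eukaryotic genome: genes of 1–8 coding
#' exons of 100–500 nt separated by introns of 60–300 nt, placed
#' left-to-right on each contig with intergenic gaps of at least 200 nt
#' (sampled up to 3x that), strands assigned independently at 0.5, and an
#' exon-skipping isoform added to 20% of genes with at least three exons.
#'
#' @param n_contigs Number of contigs; genes are distributed evenly.
#' @param contig_length Length of each contig in nt.
#' @param n_genes Total number of genes.
#' @param exon_count_range Inclusive range the per-transcript exon count
#'   is drawn from (uniform).
#' @param exon_length_range,intron_length_range Inclusive nt ranges
#'   (uniform).
#' @param min_intergenic_gap Minimum nt between consecutive gene spans;
#'   gaps are drawn uniformly from `[min, 3 * min]`.
#' @param strand_probability Probability of the `+` strand.
#' @param isoform_probability Probability that a gene with >= 3 exons
#'   carries a second, internal-exon-skipping transcript.
#' @param seed Optional integer seed making generation deterministic.
#' @return A named list of class `genome_params`.
#' @export
genome_params <- function(n_contigs = 1L, contig_length = 3e6,
                          n_genes = 100L, exon_count_range = c(1L, 8L),
                          exon_length_range = c(100L, 500L),
                          intron_length_range = c(60L, 300L),
                          min_intergenic_gap = 200L,
                          strand_probability = 0.5,
                          isoform_probability = 0.2,
                          seed = NULL) {
  stopifnot(min_intergenic_gap > 0, n_contigs >= 1, n_genes >= 1,
            exon_count_range[1] >= 1,
            exon_length_range[1] >= 1, intron_length_range[1] >= 1,
            strand_probability >= 0, strand_probability <= 1,
            isoform_probability >= 0, isoform_probability <= 1)
  structure(as.list(environment()), class = "genome_params")
}

#' Generate a synthetic reference annotation
#'
#' Genes are placed left-to-right per contig with sampled intergenic
#' gaps, so genes never overlap (on either strand) and are always
#' separated by at least `min_intergenic_gap`. Each gene has one primary
#' transcript; genes with three or more exons may gain an
#' exon-skipping isoform. Deterministic for a fixed seed.
#'
#' @param params A [genome_params()] list.
#' @return An [as_annotation()] tibble.
#' @export
generate_reference <- function(params = genome_params()) {
  stopifnot(inherits(params, "genome_params"))
  gen <- function() {
    per_contig <- diff(round(seq(0, params$n_genes,
                                 length.out = params$n_contigs + 1)))
    n <- params$n_genes
    gaps <- sample(seq.int(params$min_intergenic_gap,
                           3L * params$min_intergenic_gap), n, replace = TRUE)
    n_ex <- sample(seq.int(params$exon_count_range[1],
                           params$exon_count_range[2]), n, replace = TRUE)
    total_segs <- sum(n_ex)
    ex_len <- sample(seq.int(params$exon_length_range[1],
                             params$exon_length_range[2]),
                     total_segs, replace = TRUE)
    in_len <- sample(seq.int(params$intron_length_range[1],
                             params$intron_length_range[2]),
                     total_segs, replace = TRUE)  # last per gene unused
    strand <- ifelse(stats::runif(n) < params$strand_probability, "+", "-")
    gene_of_seg <- rep.int(seq_len(n), n_ex)
    seg_rank <- sequence(n_ex)
    # per-segment offset within its gene: cumulative exons + introns before
    step <- ex_len + in_len
    off <- stats::ave(step, gene_of_seg, FUN = function(x) {
      c(0L, cumsum(x[-length(x)]))
    })
    gene_len <- tapply(ex_len + ifelse(seg_rank < n_ex[gene_of_seg], in_len,
                                       0L),
                       gene_of_seg, sum)
    contig_of_gene <- rep.int(seq_len(params$n_contigs), per_contig)
    gene_start <- integer(n)
    pos <- 1L
    last_contig <- 0L
    for (gi in seq_len(n)) {
      if (contig_of_gene[gi] != last_contig) {
        pos <- 1L
        last_contig <- contig_of_gene[gi]
      }
      gene_start[gi] <- pos + gaps[gi]
      pos <- gene_start[gi] + gene_len[gi] - 1L
      if (pos > params$contig_length) {
        stop(sprintf(paste0("generate_reference: contig contig_%02d ",
                            "(length %d) cannot fit %d genes; increase ",
                            "contig_length or reduce n_genes"),
                     last_contig, as.integer(params$contig_length),
                     per_contig[last_contig]), call. = FALSE)
      }
    }
    gid <- sprintf("g%05d", seq_len(n))
    starts <- gene_start[gene_of_seg] + off
    tbl <- tibble::tibble(
      contig = sprintf("contig_%02d", contig_of_gene[gene_of_seg]),
      strand = strand[gene_of_seg],
      gene_id = gid[gene_of_seg],
      transcript_id = paste0(gid[gene_of_seg], ".t1"),
      start = starts,
      end = starts + ex_len - 1L,
      phase = 0L
    )
    # exon-skipping isoforms for a fraction of genes with >= 3 exons
    iso_gene <- which(n_ex >= 3 &
                        stats::runif(n) < params$isoform_probability)
    if (length(iso_gene) > 0) {
      skip_rank <- vapply(n_ex[iso_gene], function(k) {
        sample(seq.int(2L, k - 1L), 1L)
      }, integer(1))
      iso_rows <- tbl[gene_of_seg %in% iso_gene &
                        seg_rank != skip_rank[match(gene_of_seg,
                                                    iso_gene)], ]
      iso_rows$transcript_id <- sub("\\.t1$", ".t2",
                                    iso_rows$transcript_id)
      tbl <- dplyr::bind_rows(tbl, iso_rows)
    }
    tbl
  }
  tbl <- if (is.null(params$seed)) gen() else local_seed(params$seed, gen())
  as_annotation(tbl, source_label = "synthetic_reference")
}

#' Specification of defects to inject into a prediction set
#'
#' Counts may be given as integers or, when strictly below 1, as fractions
#' of the reference gene count. Genes not assigned a defect are copied
#' exactly. `n_merged` counts merged *pairs*: each consumes two adjacent
#' same-strand reference genes and emits one spanning prediction.
#' `n_fragmented` genes are each split at one intron into two disjoint
#' predictions lying fully inside the reference span.
#'
#' @param n_inexact,n_missing,n_merged,n_fragmented Defect counts (or
#'   fractions of the reference gene count).
#' @param jitter_magnitude Maximum boundary shift of an inexact gene, as a
#'   fraction of its span length (default 0.1). Shifts are also capped so
#'   a jittered gene keeps clear of the midpoints of its flanking
#'   intergenic gaps, which keeps the injected truth unambiguous under the
#'   default classifier thresholds.
#' @param spurious_transcript_rate Probability that a (non-defective)
#'   prediction gene gains an extra, structurally wrong isoform — a
#'   transcript-level false positive.
#' @param dropped_transcript_rate Probability that a prediction gene with
#'   several transcripts loses one — a transcript-level miss.
#' @param seed Optional integer seed.
#' @return A named list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(n_inexact = 0, n_missing = 0, n_merged = 0,
                              n_fragmented = 0, jitter_magnitude = 0.1,
                              spurious_transcript_rate = 0,
                              dropped_transcript_rate = 0, seed = NULL) {
  stopifnot(jitter_magnitude > 0, jitter_magnitude <= 0.5,
            spurious_transcript_rate >= 0, spurious_transcript_rate <= 1,
            dropped_transcript_rate >= 0, dropped_transcript_rate <= 1)
  structure(as.list(environment()), class = "perturbation_spec")
}

resolve_count <- function(x, total) {
  if (x > 0 && x < 1) as.integer(round(x * total)) else as.integer(x)
}

#' Inject known defects into a reference annotation
#'
#' Produces a prediction set by perturbing a synthetic reference, together
#' with per-gene truth labels. Defects are assigned to disjoint gene
#' subsets by seeded sampling, in the fixed order merged, fragmented,
#' missing, inexact (remainder exact):
#' \describe{
#'   \item{exact}{gene copied verbatim;}
#'   \item{inexact}{both span boundaries shifted by at least 1 nt and at
#'     most `jitter_magnitude` of the gene length, never crossing the
#'     midpoint of a flanking intergenic gap;}
#'   \item{missing}{gene omitted from the predictions;}
#'   \item{merged}{two adjacent same-strand genes replaced by a single
#'     prediction whose one transcript chains both genes' segments
#'     (covering each reference completely);}
#'   \item{fragmented}{a multi-exon gene replaced by two disjoint
#'     predictions split at an intron, each fully inside the reference
#'     span.}
#' }
#'
#' @param reference An annotation from [generate_reference()] (the
#'   generator's separation guarantees are assumed).
#' @param spec A [perturbation_spec()].
#' @param seed Seed overriding `spec$seed`.
#' @return A list: `predictions` (annotation), `truth` with
#'   `reference_genes` (`gene_id`, `outcome`, `prediction_ids` list) and
#'   `prediction_genes` (`gene_id`, `role`, `reference_ids` list), plus
#'   `spurious_transcripts` / `dropped_transcripts` id vectors.
#' @export
inject_defects <- function(reference, spec = perturbation_spec(),
                           seed = NULL) {
  seed <- seed %||% spec$seed
  run <- function() inject_defects_impl(reference, spec)
  if (is.null(seed)) run() else local_seed(seed, run())
}

inject_defects_impl <- function(reference, spec) {
  gs <- gene_spans(reference)
  n <- nrow(gs)
  n_merged <- resolve_count(spec$n_merged, n)
  n_fragmented <- resolve_count(spec$n_fragmented, n)
  n_missing <- resolve_count(spec$n_missing, n)
  n_inexact <- resolve_count(spec$n_inexact, n)
  if (2L * n_merged + n_fragmented + n_missing + n_inexact > n) {
    stop("inject_defects: requested defects exceed the gene count",
         call. = FALSE)
  }
  ann <- tibble::as_tibble(reference)
  seg_by_gene <- split(ann, ann$gene_id)
  used <- character(0)
  outcome <- stats::setNames(rep("exact", n), gs$gene_id)
  ref_pred <- stats::setNames(vector("list", n), gs$gene_id)

  pred_rows <- list()
  pred_truth <- list()
  add_pred <- function(rows, role, ref_ids) {
    pred_rows[[length(pred_rows) + 1L]] <<- rows
    pred_truth[[length(pred_truth) + 1L]] <<- tibble::tibble(
      gene_id = rows$gene_id[1], role = role,
      reference_ids = list(ref_ids))
    for (r in ref_ids) {
      ref_pred[[r]] <<- c(ref_pred[[r]], rows$gene_id[1])
    }
  }

  ## merged: adjacent same-strand pairs, disjoint
  if (n_merged > 0) {
    cand <- adjacent_same_strand_pairs(gs)
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    taken <- 0L
    for (i in seq_len(nrow(cand))) {
      if (taken == n_merged) break
      g1 <- cand$gene_1[i]; g2 <- cand$gene_2[i]
      if (g1 %in% used || g2 %in% used) next
      used <- c(used, g1, g2)
      taken <- taken + 1L
      outcome[c(g1, g2)] <- "merged"
      pid <- sprintf("p_merged_%04d", taken)
      segs <- dplyr::bind_rows(primary_transcript(seg_by_gene[[g1]]),
                               primary_transcript(seg_by_gene[[g2]]))
      segs$gene_id <- pid
      segs$transcript_id <- paste0(pid, ".t1")
      add_pred(segs[order(segs$start), ], "merged", c(g1, g2))
    }
    if (taken < n_merged) {
      stop(sprintf(paste0("inject_defects: only %d disjoint adjacent ",
                          "same-strand pairs available for %d requested ",
                          "merges"), taken, n_merged), call. = FALSE)
    }
  }

  ## fragmented: multi-exon genes split at an intron
  if (n_fragmented > 0) {
    multi <- gs$gene_id[vapply(gs$gene_id, function(g) {
      nrow(primary_transcript(seg_by_gene[[g]])) >= 2
    }, logical(1))]
    multi <- setdiff(multi, used)
    if (length(multi) < n_fragmented) {
      stop("inject_defects: not enough unused multi-exon genes to fragment",
           call. = FALSE)
    }
    chosen <- sample(multi, n_fragmented)
    for (g in chosen) {
      used <- c(used, g)
      outcome[g] <- "fragmented"
      segs <- primary_transcript(seg_by_gene[[g]])
      segs <- segs[order(segs$start), ]
      cut <- if (nrow(segs) == 2) 1L else sample.int(nrow(segs) - 1L, 1L)
      for (part in 1:2) {
        sel <- if (part == 1) seq_len(cut) else seq.int(cut + 1L, nrow(segs))
        pid <- sprintf("p_%s_frag%d", g, part)
        ps <- segs[sel, ]
        ps$gene_id <- pid
        ps$transcript_id <- paste0(pid, ".t1")
        add_pred(ps, "fragment", g)
      }
    }
  }

  ## missing
  if (n_missing > 0) {
    pool <- setdiff(gs$gene_id, used)
    chosen <- sample(pool, n_missing)
    used <- c(used, chosen)
    outcome[chosen] <- "missing"
  }

  ## inexact: jittered copies
  if (n_inexact > 0) {
    pool <- setdiff(gs$gene_id, used)
    chosen <- sample(pool, n_inexact)
    used <- c(used, chosen)
    for (g in chosen) {
      outcome[g] <- "inexact"
      jittered <- jitter_gene(seg_by_gene[[g]], gs, spec$jitter_magnitude)
      pid <- paste0("p_", g)
      jittered$gene_id <- pid
      jittered$transcript_id <- sub(g, pid, jittered$transcript_id,
                                    fixed = TRUE)
      add_pred(jittered, "inexact", g)
    }
  }

  ## exact copies for the remainder (bulk)
  rest <- setdiff(gs$gene_id, used)
  if (length(rest) > 0) {
    segs <- ann[ann$gene_id %in% rest, , drop = FALSE]
    old_ids <- segs$gene_id
    segs$transcript_id <- paste0(
      "p_", old_ids, sub("^[^.]*", "", segs$transcript_id))
    segs$gene_id <- paste0("p_", old_ids)
    pred_rows[[length(pred_rows) + 1L]] <- segs
    pred_truth[[length(pred_truth) + 1L]] <- tibble::tibble(
      gene_id = paste0("p_", rest), role = "exact",
      reference_ids = lapply(rest, identity))
    for (r in rest) ref_pred[[r]] <- c(ref_pred[[r]], paste0("p_", r))
  }

  predictions <- dplyr::bind_rows(pred_rows)

  ## transcript-level noise
  spurious <- character(0)
  dropped <- character(0)
  if (spec$spurious_transcript_rate > 0 || spec$dropped_transcript_rate > 0) {
    by_gene <- split(predictions, predictions$gene_id)
    out_rows <- list()
    for (g in names(by_gene)) {
      rows <- by_gene[[g]]
      txs <- unique(rows$transcript_id)
      if (length(txs) > 1 &&
            stats::runif(1) < spec$dropped_transcript_rate) {
        drop_tx <- txs[length(txs)]
        rows <- rows[rows$transcript_id != drop_tx, ]
        dropped <- c(dropped, drop_tx)
        txs <- unique(rows$transcript_id)
      }
      if (stats::runif(1) < spec$spurious_transcript_rate) {
        prim <- rows[rows$transcript_id == txs[1], ]
        prim <- prim[order(prim$start), ]
        extra <- if (nrow(prim) >= 3) {
          prim[-2, ]
        } else {
          trimmed <- prim
          trim <- min(30L, trimmed$end[1] - trimmed$start[1])
          trimmed$start[1] <- trimmed$start[1] + trim
          trimmed
        }
        extra$transcript_id <- paste0(g, ".spurious")
        spurious <- c(spurious, paste0(g, ".spurious"))
        rows <- dplyr::bind_rows(rows, extra)
      }
      out_rows[[length(out_rows) + 1L]] <- rows
    }
    predictions <- dplyr::bind_rows(out_rows)
  }

  truth_ref <- tibble::tibble(
    gene_id = gs$gene_id,
    outcome = unname(outcome[gs$gene_id]),
    prediction_ids = unname(ref_pred[gs$gene_id])
  )
  truth_ref$prediction_ids <- lapply(truth_ref$prediction_ids,
                                     function(x) x %||% character(0))
  list(
    predictions = as_annotation(predictions,
                                source_label = "synthetic_prediction"),
    truth = list(
      reference_genes = truth_ref,
      prediction_genes = dplyr::bind_rows(pred_truth),
      spurious_transcripts = spurious,
      dropped_transcripts = dropped
    )
  )
}

primary_transcript <- function(rows) {
  tx <- sort(unique(rows$transcript_id))[1]
  rows[rows$transcript_id == tx, , drop = FALSE]
}

# consecutive same-strand genes within a contig's per-strand gene order
adjacent_same_strand_pairs <- function(gs) {
  gs |>
    dplyr::arrange(.data$contig, .data$strand, .data$start) |>
    dplyr::group_by(.data$contig, .data$strand) |>
    dplyr::reframe(gene_1 = .data$gene_id[-dplyr::n()],
                   gene_2 = .data$gene_id[-1L])
}

# shift both span boundaries of a gene by at least 1 nt, staying on the
# near side of the midpoints of the flanking intergenic gaps
jitter_gene <- function(rows, gs, jitter_magnitude) {
  g <- rows$gene_id[1]
  i <- match(g, gs$gene_id)
  span_start <- gs$start[i]; span_end <- gs$end[i]
  len <- span_end - span_start + 1L
  on_contig <- gs[gs$contig == gs$contig[i], ]
  j <- match(g, on_contig$gene_id)
  prev_end <- if (j > 1) on_contig$end[j - 1L] else 0L
  next_start <- if (j < nrow(on_contig)) {
    on_contig$start[j + 1L]
  } else {
    span_end + 10L * len  # free space past the last gene
  }
  left_gap <- span_start - prev_end - 1L
  right_gap <- next_start - span_end - 1L
  max_mag <- max(1L, as.integer(floor(jitter_magnitude * len)))

  rows_sorted <- rows[order(rows$start), ]
  by_tx <- split(rows_sorted, rows_sorted$transcript_id)
  first_lens <- vapply(by_tx, function(t) t$end[1] - t$start[1] + 1L,
                       numeric(1))
  last_lens <- vapply(by_tx, function(t) {
    t$end[nrow(t)] - t$start[nrow(t)] + 1L
  }, numeric(1))

  delta_start <- pick_shift(max_mag,
                            ext_max = max(0L, floor(left_gap / 2) - 1L),
                            trim_max = max(0L, min(first_lens) - 1L))
  # when a transcript is single-exon its first and last segment coincide,
  # so an end trim must leave room for whatever the start trim consumed
  single <- vapply(by_tx, nrow, 0L) == 1L
  eff_last <- last_lens
  if (delta_start > 0L && any(single)) {
    eff_last[single] <- eff_last[single] - delta_start
  }
  delta_end <- pick_shift(max_mag,
                          ext_max = max(0L, floor(right_gap / 2) - 1L),
                          trim_max = max(0L, min(eff_last) - 1L))
  new_start <- span_start + delta_start  # negative delta extends leftward
  new_end <- span_end - delta_end        # negative delta extends rightward

  out <- rows
  touch_start <- out$start == span_start
  touch_end <- out$end == span_end
  out$start[touch_start] <- new_start
  # a trim can also eat into segments beginning after the old span start
  out$start <- pmax(out$start, new_start)
  out$end[touch_end] <- new_end
  out$end <- pmin(out$end, new_end)
  out
}

# a signed shift with magnitude in [1, max_mag], respecting extension and
# trim caps; positive = inward (trim), negative = outward (extension)
pick_shift <- function(max_mag, ext_max, trim_max) {
  if (ext_max == 0L && trim_max == 0L) {
    stop("jitter_gene: no room to shift a boundary; lower jitter_magnitude ",
         "or raise min_intergenic_gap", call. = FALSE)
  }
  mag <- sample.int(max_mag, 1L)
  outward <- stats::runif(1) < 0.5
  if (outward && ext_max > 0L) {
    -min(mag, ext_max)
  } else if (trim_max > 0L) {
    min(mag, trim_max)
  } else {
    -min(mag, ext_max)
  }
}
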