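# Transcript-level matching and exon/intron tallies within a classified
# gene group. All overlap weights use CDS footprints (unions of coding
# segments), never spans, so long introns cannot fabricate overlap.

#' Match prediction to reference transcripts within a gene group
#'
#' Pairs prediction and reference transcripts one-to-one so that the total
#' nucleotide overlap between paired CDS footprints is maximal (an exact
#' assignment, not a greedy one). Pairs with zero overlap are never
#' created. Unpaired reference transcripts are *missing*; unpaired
#' prediction transcripts are *false positives*. Ties between equally
#' optimal assignments are broken toward the transcript pair that comes
#' first by genomic start, reference first.
#'
#' @param predictions,references [as_annotation()] tibbles restricted to
#'   the gene group being compared (for merged or fragmented loci, all
#'   participating genes pooled).
#' @return A list of class `transcript_assignment`: `pairs` (tibble
#'   `prediction_id`, `reference_id`, `overlap`), `total_overlap`,
#'   `missing_refs`, `false_positive_preds`.
#' @export
match_transcripts <- function(predictions, references) {
  pred_tx <- split_tx(predictions)
  ref_tx <- split_tx(references)
  if (length(pred_tx$ids) == 0 && length(ref_tx$ids) == 0) {
    stop("match_transcripts: both transcript groups are empty", call. = FALSE)
  }
  w <- list(row = character(0), col = character(0), weight = numeric(0))
  for (i in seq_along(pred_tx$ids)) {
    for (j in seq_along(ref_tx$ids)) {
      if (pred_tx$contig[i] != ref_tx$contig[j] ||
          pred_tx$strand[i] != ref_tx$strand[j]) next
      ov <- footprint_overlap(pred_tx$starts[[i]], pred_tx$ends[[i]],
                              ref_tx$starts[[j]], ref_tx$ends[[j]])
      if (ov > 0) {
        w$row <- c(w$row, ref_tx$ids[j])
        w$col <- c(w$col, pred_tx$ids[i])
        w$weight <- c(w$weight, ov)
      }
    }
  }
  asg <- max_weight_assignment(as.data.frame(w),
                               row_order = ref_tx$ids,
                               col_order = pred_tx$ids)
  pairs <- tibble::tibble(prediction_id = asg$col,
                          reference_id = asg$row,
                          overlap = asg$weight)
  structure(list(
    pairs = pairs,
    total_overlap = sum(pairs$overlap),
    missing_refs = setdiff(ref_tx$ids, pairs$reference_id),
    false_positive_preds = setdiff(pred_tx$ids, pairs$prediction_id)
  ), class = "transcript_assignment")
}

#' @export
print.transcript_assignment <- function(x, ...) {
  cat(sprintf(paste0("<transcript_assignment> %d pair(s), total overlap ",
                     "%d nt, %d missing reference(s), %d false positive(s)\n"),
              nrow(x$pairs), x$total_overlap, length(x$missing_refs),
              length(x$false_positive_preds)))
  invisible(x)
}

# transcript ids ordered by genomic start, with per-transcript sorted
# segment vectors
split_tx <- function(ann) {
  if (nrow(ann) == 0) {
    return(list(ids = character(0), contig = character(0),
                strand = character(0), starts = list(), ends = list()))
  }
  ts <- transcript_spans(ann)
  idx <- split(seq_len(nrow(ann)), ann$transcript_id)[ts$transcript_id]
  starts <- lapply(idx, function(i) sort(ann$start[i]))
  ends <- lapply(idx, function(i) ann$end[i][order(ann$start[i])])
  list(ids = ts$transcript_id, contig = ts$contig, strand = ts$strand,
       starts = starts, ends = ends)
}

#' Tally matched, missing and false-positive sub-features
#'
#' Within each assigned transcript pair, exons (coding segments) and
#' introns are themselves paired by maximum-overlap assignment — for
#' collinear, non-overlapping features this coincides with matching in
#' genomic order — and every unpaired feature is counted missing (reference
#' side) or false positive (prediction side). All features of unmatched
#' reference transcripts count as missing; all features of false-positive
#' prediction transcripts count as false positives. Exon tallies are
#' additionally broken down by the exon's position class (initial,
#' internal, terminal, single), and exact-coordinate match counts are
#' reported for the strict stringency used by accuracy statistics.
#'
#' @param assignment A [match_transcripts()] result for the group.
#' @param predictions,references The same annotation subsets the
#'   assignment was computed from.
#' @return A list of class `feature_tally`: `tally`, a tibble with one row
#'   per level (`transcript`, `exon`, `intron`) and columns `matched`,
#'   `missing`, `false_positive`, `exact`; and `exon_positions`, a tibble
#'   of the same counts per position class (matched/missing classed by the
#'   reference exon, false positives by the prediction exon).
#' @export
tally_subfeatures <- function(assignment, predictions, references) {
  pred_cls <- cds_position_class(predictions)
  ref_cls <- cds_position_class(references)
  pred_introns <- derive_introns(predictions)
  ref_introns <- derive_introns(references)

  pos_levels <- c("initial", "internal", "terminal", "single")
  pos_counts <- stats::setNames(rep(0L, 4), pos_levels)
  ex_matched <- ex_missing <- ex_fp <- pos_counts
  counts <- c(exon_matched = 0L, exon_exact = 0L,
              intron_matched = 0L, intron_exact = 0L)

  ref_ex_by_tx <- split(ref_cls, ref_cls$transcript_id)
  pred_ex_by_tx <- split(pred_cls, pred_cls$transcript_id)
  ref_in_by_tx <- split(ref_introns, ref_introns$transcript_id)
  pred_in_by_tx <- split(pred_introns, pred_introns$transcript_id)

  empty_feat <- tibble::tibble(start = integer(0), end = integer(0),
                               position_class = character(0))

  for (k in seq_len(nrow(assignment$pairs))) {
    p <- assignment$pairs$prediction_id[k]
    r <- assignment$pairs$reference_id[k]
    m <- match_features(pred_ex_by_tx[[p]] %||% empty_feat,
                        ref_ex_by_tx[[r]] %||% empty_feat)
    counts["exon_matched"] <- counts["exon_matched"] + m$n_matched
    counts["exon_exact"] <- counts["exon_exact"] + m$n_exact
    ex_matched <- ex_matched + m$ref_matched_by_class
    ex_missing <- ex_missing + m$ref_missing_by_class
    ex_fp <- ex_fp + m$pred_fp_by_class
    mi <- match_features(pred_in_by_tx[[p]] %||% empty_feat,
                         ref_in_by_tx[[r]] %||% empty_feat)
    counts["intron_matched"] <- counts["intron_matched"] + mi$n_matched
    counts["intron_exact"] <- counts["intron_exact"] + mi$n_exact
  }

  # features of unmatched transcripts
  for (r in assignment$missing_refs) {
    feats <- ref_ex_by_tx[[r]]
    if (!is.null(feats)) {
      tb <- table(factor(feats$position_class, levels = pos_levels))
      ex_missing <- ex_missing + as.integer(tb)
    }
  }
  for (p in assignment$false_positive_preds) {
    feats <- pred_ex_by_tx[[p]]
    if (!is.null(feats)) {
      tb <- table(factor(feats$position_class, levels = pos_levels))
      ex_fp <- ex_fp + as.integer(tb)
    }
  }

  n_ref_tx <- length(unique(references$transcript_id))
  n_pred_tx <- length(unique(predictions$transcript_id))
  n_pairs <- nrow(assignment$pairs)
  tx_exact <- sum(vapply(seq_len(n_pairs), function(k) {
    identical_chain(pred_ex_by_tx[[assignment$pairs$prediction_id[k]]],
                    ref_ex_by_tx[[assignment$pairs$reference_id[k]]])
  }, logical(1)))

  n_ref_ex <- nrow(ref_cls); n_pred_ex <- nrow(pred_cls)
  n_ref_in <- nrow(ref_introns); n_pred_in <- nrow(pred_introns)

  tally <- tibble::tibble(
    level = c("transcript", "exon", "intron"),
    matched = c(n_pairs, unname(counts["exon_matched"]),
                unname(counts["intron_matched"])),
    missing = c(n_ref_tx - n_pairs,
                n_ref_ex - unname(counts["exon_matched"]),
                n_ref_in - unname(counts["intron_matched"])),
    false_positive = c(n_pred_tx - n_pairs,
                       n_pred_ex - unname(counts["exon_matched"]),
                       n_pred_in - unname(counts["intron_matched"])),
    exact = c(tx_exact, unname(counts["exon_exact"]),
              unname(counts["intron_exact"]))
  )
  exon_positions <- tibble::tibble(
    position_class = pos_levels,
    matched = unname(ex_matched),
    missing = unname(ex_missing),
    false_positive = unname(ex_fp)
  )
  structure(list(tally = tally, exon_positions = exon_positions),
            class = "feature_tally")
}

#' @export
print.feature_tally <- function(x, ...) {
  cat("<feature_tally>\n")
  print(x$tally)
  invisible(x)
}

# Pair prediction features against reference features of one transcript
# pair by maximum-overlap assignment; count exact-coordinate pairs.
match_features <- function(pred, ref) {
  pos_levels <- c("initial", "internal", "terminal", "single")
  zero <- stats::setNames(rep(0L, 4), pos_levels)
  np <- nrow(pred); nr <- nrow(ref)
  if (np == 0 || nr == 0) {
    return(list(
      n_matched = 0L, n_exact = 0L,
      ref_matched_by_class = zero,
      ref_missing_by_class = zero + class_table(ref, pos_levels),
      pred_fp_by_class = zero + class_table(pred, pos_levels)
    ))
  }
  pred <- pred[order(pred$start), , drop = FALSE]
  ref <- ref[order(ref$start), , drop = FALSE]
  lo <- outer(pred$start, ref$start, pmax)
  hi <- outer(pred$end, ref$end, pmin)
  ov <- matrix(pmax(0L, hi - lo + 1L), nrow = np)
  idx <- which(ov > 0, arr.ind = TRUE)
  idx <- matrix(idx, ncol = 2)
  asg <- max_weight_assignment(
    data.frame(row = paste0("r", idx[, 2]), col = paste0("p", idx[, 1]),
               weight = ov[idx]),
    row_order = paste0("r", seq_len(nr)),
    col_order = paste0("p", seq_len(np)))
  ri <- as.integer(sub("^r", "", asg$row))
  pi <- as.integer(sub("^p", "", asg$col))
  exact <- sum(pred$start[pi] == ref$start[ri] & pred$end[pi] == ref$end[ri])
  ref_classes <- if (nr > 0 && "position_class" %in% names(ref)) {
    ref$position_class
  } else {
    rep(NA_character_, nr)
  }
  pred_classes <- if (np > 0 && "position_class" %in% names(pred)) {
    pred$position_class
  } else {
    rep(NA_character_, np)
  }
  cls_count <- function(cls) {
    as.integer(table(factor(cls, levels = pos_levels)))
  }
  list(
    n_matched = nrow(asg),
    n_exact = exact,
    ref_matched_by_class = stats::setNames(cls_count(ref_classes[ri]),
                                           pos_levels),
    ref_missing_by_class = stats::setNames(
      cls_count(ref_classes[setdiff(seq_len(nr), ri)]), pos_levels),
    pred_fp_by_class = stats::setNames(
      cls_count(pred_classes[setdiff(seq_len(np), pi)]), pos_levels)
  )
}

class_table <- function(feats, pos_levels) {
  if (nrow(feats) == 0 || !"position_class" %in% names(feats)) {
    return(stats::setNames(rep(0L, length(pos_levels)), pos_levels))
  }
  stats::setNames(
    as.integer(table(factor(feats$position_class, levels = pos_levels))),
    pos_levels)
}

identical_chain <- function(pred, ref) {
  if (is.null(pred) || is.null(ref)) return(FALSE)
  if (nrow(pred) != nrow(ref)) return(FALSE)
  po <- order(pred$start); ro <- order(ref$start)
  all(pred$start[po] == ref$start[ro]) && all(pred$end[po] == ref$end[ro])
}
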