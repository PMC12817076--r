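# Gene-level outcome classification: exact / inexact / missing / merged /
# fragmented, plus unassigned predictions. Purely coordinate-based and
# strand-aware; spans are CDS extrema.

#' Thresholds for the gene outcome classifier
#'
#' @param merged_ref_coverage A prediction is *merged* when it covers two
#'   or more reference genes, each by strictly more than this fraction of
#'   the reference's span length (default 0.5).
#' @param fragment_pred_coverage A reference is *fragmented* when two or
#'   more predictions each place at least this fraction of their own span
#'   inside the reference span (default 0.5, non-strict).
#' @param fragment_mutual_overlap_max Fragments must be "separate": the
#'   pairwise overlap between two fragments may not exceed this fraction of
#'   the shorter fragment (default 0, i.e. disjoint fragments).
#' @return A named list of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(merged_ref_coverage = 0.5,
                                  fragment_pred_coverage = 0.5,
                                  fragment_mutual_overlap_max = 0) {
  vals <- c(merged_ref_coverage, fragment_pred_coverage,
            fragment_mutual_overlap_max)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("classifier thresholds must lie in [0, 1]", call. = FALSE)
  }
  structure(list(merged_ref_coverage = merged_ref_coverage,
                 fragment_pred_coverage = fragment_pred_coverage,
                 fragment_mutual_overlap_max = fragment_mutual_overlap_max),
            class = "classifier_thresholds")
}

span_granges <- function(spans) {
  GenomicRanges::GRanges(
    seqnames = spans$contig,
    ranges = IRanges::IRanges(start = spans$start, end = spans$end),
    strand = spans$strand
  )
}

#' Classify reference gene loci against a prediction set
#'
#' Every reference gene receives exactly one outcome:
#' \describe{
#'   \item{merged}{a single prediction spans two or more reference genes,
#'     covering each by more than `merged_ref_coverage` of its length —
#'     typically an intergenic region mistaken for an intron;}
#'   \item{fragmented}{two or more predictions each lie (by at least
#'     `fragment_pred_coverage` of their own span) inside one reference
#'     gene, on separate portions of it — typically an intron mistaken for
#'     an intergenic region;}
#'   \item{exact}{the remaining one-to-one match has identical span
#'     boundaries;}
#'   \item{inexact}{the one-to-one match overlaps but differs at the 5' or
#'     3' boundary;}
#'   \item{missing}{no prediction is matched to the reference.}
#' }
#' Classes are resolved in the order merged, fragmented, one-to-one; each
#' step consumes its participating genes, which guarantees the outcomes
#' partition the reference set. Remaining one-to-one candidates are
#' resolved by maximum-weight assignment on span overlap, never greedily.
#' Predictions consumed by no class are reported with outcome
#' `unassigned_prediction` (they are not a gene-level defect of any
#' reference, but feed false-positive tallies downstream).
#'
#' Matching is restricted to identical (contig, strand): opposite-strand
#' overlap is never a match.
#'
#' @param predictions,references [as_annotation()] tibbles.
#' @param thresholds A [classifier_thresholds()] list.
#' @return A tibble with one row per classification: `outcome`,
#'   `reference_ids` and `prediction_ids` (list columns), `contig`,
#'   `strand`, and `coverages`, a list column of per-pair tibbles
#'   (`prediction_id`, `reference_id`, `overlap`, `ref_coverage`,
#'   `pred_coverage`).
#' @export
classify_genes <- function(predictions, references,
                           thresholds = classifier_thresholds()) {
  if (!inherits(thresholds, "classifier_thresholds")) {
    thresholds <- do.call(classifier_thresholds, as.list(thresholds))
  }
  ref_spans <- gene_spans(references)
  pred_spans <- gene_spans(predictions)
  warn_internal_overlaps(ref_spans, "references")
  warn_internal_overlaps(pred_spans, "predictions")

  if (nrow(pred_spans) > 0 && nrow(ref_spans) > 0) {
    hits <- GenomicRanges::findOverlaps(span_granges(pred_spans),
                                        span_granges(ref_spans),
                                        ignore.strand = FALSE)
    pi <- S4Vectors::queryHits(hits); ri <- S4Vectors::subjectHits(hits)
  } else {
    pi <- ri <- integer(0)
  }
  ov <- pmax(0L, pmin(pred_spans$end[pi], ref_spans$end[ri]) -
                   pmax(pred_spans$start[pi], ref_spans$start[ri]) + 1L)
  pairs <- tibble::tibble(
    prediction_id = pred_spans$gene_id[pi],
    reference_id = ref_spans$gene_id[ri],
    overlap = ov,
    ref_coverage = ov / ref_spans$length[ri],
    pred_coverage = ov / pred_spans$length[pi]
  )

  ref_used <- stats::setNames(rep(FALSE, nrow(ref_spans)), ref_spans$gene_id)
  pred_used <- stats::setNames(rep(FALSE, nrow(pred_spans)),
                               pred_spans$gene_id)
  # accumulator; coverage sub-tables are picked out through per-id row
  # indexes so classification stays O(overlap pairs)
  rows_by_ref <- split(seq_len(nrow(pairs)), pairs$reference_id)
  rows_by_pred <- split(seq_len(nrow(pairs)), pairs$prediction_id)
  acc <- new.env(parent = emptyenv())
  acc$outcome <- character(0)
  acc$refs <- list()
  acc$preds <- list()
  acc$cov <- list()
  emit <- function(outcome, refs, preds) {
    k <- length(acc$outcome) + 1L
    acc$outcome[k] <- outcome
    acc$refs[[k]] <- as.character(refs)
    acc$preds[[k]] <- as.character(preds)
    idx <- intersect(unlist(rows_by_ref[refs], use.names = FALSE),
                     unlist(rows_by_pred[preds], use.names = FALSE))
    acc$cov[[k]] <- pairs[idx, , drop = FALSE]
  }

  ## --- step 1: merged predictions -------------------------------------
  qualifying <- pairs[pairs$ref_coverage > thresholds$merged_ref_coverage, ,
                      drop = FALSE]
  cand_preds <- names(which(table(qualifying$prediction_id) >= 2))
  # deterministic order: by genomic position of the prediction
  cand_preds <- pred_spans$gene_id[pred_spans$gene_id %in% cand_preds]
  for (p in cand_preds) {
    refs <- qualifying$reference_id[qualifying$prediction_id == p]
    refs <- refs[!ref_used[refs]]
    if (length(refs) >= 2 && !pred_used[p]) {
      ref_used[refs] <- TRUE
      pred_used[p] <- TRUE
      emit("merged", refs, p)
    }
  }

  ## --- step 2: fragmented references ----------------------------------
  frag_pairs <- pairs[pairs$pred_coverage >= thresholds$fragment_pred_coverage, ,
                      drop = FALSE]
  cand_refs <- names(which(table(frag_pairs$reference_id) >= 2))
  cand_refs <- ref_spans$gene_id[ref_spans$gene_id %in% cand_refs]
  for (r in cand_refs) {
    if (ref_used[r]) next
    preds <- frag_pairs$prediction_id[frag_pairs$reference_id == r]
    preds <- preds[!pred_used[preds]]
    if (length(preds) < 2) next
    # keep fragments in genomic order, greedily enforcing pairwise separation
    preds <- pred_spans$gene_id[pred_spans$gene_id %in% preds]
    ps <- pred_spans[match(preds, pred_spans$gene_id), , drop = FALSE]
    kept <- integer(0)
    for (k in seq_along(preds)) {
      ok <- TRUE
      for (j in kept) {
        mut_ov <- pmax(0L, pmin(ps$end[k], ps$end[j]) -
                             pmax(ps$start[k], ps$start[j]) + 1L)
        shorter <- min(ps$length[k], ps$length[j])
        if (mut_ov > thresholds$fragment_mutual_overlap_max * shorter) {
          ok <- FALSE
          break
        }
      }
      if (ok) kept <- c(kept, k)
    }
    if (length(kept) >= 2) {
      sel <- preds[kept]
      ref_used[r] <- TRUE
      pred_used[sel] <- TRUE
      emit("fragmented", r, sel)
    }
  }

  ## --- step 3: one-to-one assignment on remaining overlaps ------------
  rem <- pairs[!ref_used[pairs$reference_id] &
                 !pred_used[pairs$prediction_id], , drop = FALSE]
  if (nrow(rem) > 0) {
    comp <- overlap_components(rem)
    ref_start <- stats::setNames(ref_spans$start, ref_spans$gene_id)
    ref_end <- stats::setNames(ref_spans$end, ref_spans$gene_id)
    pred_start <- stats::setNames(pred_spans$start, pred_spans$gene_id)
    pred_end <- stats::setNames(pred_spans$end, pred_spans$gene_id)
    for (cmp in comp) {
      if (nrow(cmp) == 1L) {
        asg <- cmp[, c("reference_id", "prediction_id")]
        names(asg) <- c("row", "col")
      } else {
        asg <- max_weight_assignment(
          data.frame(row = cmp$reference_id, col = cmp$prediction_id,
                     weight = cmp$overlap),
          row_order = ref_spans$gene_id[ref_spans$gene_id %in%
                                          cmp$reference_id],
          col_order = pred_spans$gene_id[pred_spans$gene_id %in%
                                           cmp$prediction_id])
      }
      for (k in seq_len(nrow(asg))) {
        r <- asg$row[k]; p <- asg$col[k]
        ref_used[r] <- TRUE
        pred_used[p] <- TRUE
        outcome <- if (ref_start[r] == pred_start[p] &&
                         ref_end[r] == pred_end[p]) {
          "exact"
        } else {
          "inexact"
        }
        emit(outcome, r, p)
      }
    }
  }

  ## --- step 4: leftovers ----------------------------------------------
  for (r in ref_spans$gene_id[!ref_used]) emit("missing", r, character(0))
  for (p in pred_spans$gene_id[!pred_used]) {
    emit("unassigned_prediction", character(0), p)
  }

  first_ref <- vapply(acc$refs, function(x) {
    if (length(x) > 0) x[1] else NA_character_
  }, "")
  first_pred <- vapply(acc$preds, function(x) {
    if (length(x) > 0) x[1] else NA_character_
  }, "")
  anchor_ref <- match(first_ref, ref_spans$gene_id)
  anchor_pred <- match(first_pred, pred_spans$gene_id)
  out <- tibble::tibble(
    outcome = acc$outcome,
    reference_ids = acc$refs,
    prediction_ids = acc$preds,
    contig = ifelse(is.na(anchor_ref), pred_spans$contig[anchor_pred],
                    ref_spans$contig[anchor_ref]),
    strand = ifelse(is.na(anchor_ref), pred_spans$strand[anchor_pred],
                    ref_spans$strand[anchor_ref]),
    coverages = acc$cov
  )
  if (nrow(out) == 0) {
    out <- tibble::tibble(outcome = character(), reference_ids = list(),
                          prediction_ids = list(), contig = character(),
                          strand = character(), coverages = list())
  }
  out$outcome <- factor(out$outcome,
                        levels = c("exact", "inexact", "missing", "merged",
                                   "fragmented", "unassigned_prediction"))
  out[order(out$contig,
            vapply(out$reference_ids, function(x) length(x) == 0, TRUE)), ,
      drop = FALSE]
}

# Connected components of the remaining bipartite overlap graph, so that
# the assignment DP only ever sees one locus neighbourhood at a time.
overlap_components <- function(pairs) {
  refs <- unique(pairs$reference_id)
  preds <- unique(pairs$prediction_id)
  id <- c(refs, preds)
  parent <- seq_along(id)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ri <- match(pairs$reference_id, id)
  pi <- match(pairs$prediction_id, id)
  for (k in seq_len(nrow(pairs))) {
    a <- find(ri[k]); b <- find(pi[k])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(ri, find, integer(1))
  unname(split(pairs, comp))
}

warn_internal_overlaps <- function(spans, label) {
  if (nrow(spans) < 2) return(invisible())
  sp <- spans[order(spans$contig, spans$strand, spans$start), ]
  same <- sp$contig[-1] == sp$contig[-nrow(sp)] &
    sp$strand[-1] == sp$strand[-nrow(sp)]
  ovl <- same & sp$start[-1] <= cummax_by(sp$end, sp$contig, sp$strand)[-nrow(sp)]
  if (any(ovl)) {
    message("note: ", sum(ovl), " same-strand overlapping gene pair(s) within ",
            label)
  }
  invisible()
}

cummax_by <- function(x, g1, g2) {
  key <- paste(g1, g2)
  unlist(lapply(split(x, factor(key, levels = unique(key))), cummax),
         use.names = FALSE)
}

#' Flatten a classification to one row per reference gene
#'
#' Convenience view of [classify_genes()] output for comparing against
#' truth labels: each reference gene with its outcome and the prediction
#' id(s) involved.
#'
#' @param classification Output of [classify_genes()].
#' @return A tibble: `reference_id`, `outcome`, `prediction_ids` (list).
#' @export
outcome_by_reference <- function(classification) {
  cl <- classification[vapply(classification$reference_ids, length, 1L) > 0, ,
                       drop = FALSE]
  tibble::tibble(
    reference_id = unlist(cl$reference_ids, use.names = FALSE),
    outcome = rep(as.character(cl$outcome),
                  vapply(cl$reference_ids, length, 1L)),
    prediction_ids = rep(cl$prediction_ids,
                         vapply(cl$reference_ids, length, 1L))
  )
}
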