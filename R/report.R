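# Multi-pipeline agreement partition and the consolidated per-organism
# evaluation report.

#' Partition reference genes by the pipelines that recover them
#'
#' Runs [classify_genes()] independently for each prediction set and
#' assigns every reference gene to the subset of pipelines whose outcome
#' for it is a match (exact or inexact). Counts are reported raw and per
#' 1000 reference genes. A parallel partition is emitted for each
#' defective outcome (merged, fragmented, missing): the subset of
#' pipelines sharing that defect at the gene.
#'
#' @param prediction_sets Named list of [as_annotation()] tibbles, one per
#'   pipeline (at least two).
#' @param references An [as_annotation()] tibble.
#' @param thresholds A [classifier_thresholds()] list.
#' @return A list of class `agreement_partition`: `cells`, a tibble
#'   (`category`, `pipelines` — `"+"`-joined subset label, `n_pipelines`,
#'   `n`, `per_1000`); `n_unmatched` (genes matched by no pipeline);
#'   `total_reference_genes`; and `outcomes`, the underlying gene-by-
#'   pipeline outcome tibble.
#' @export
agreement_partition <- function(prediction_sets, references,
                                thresholds = classifier_thresholds()) {
  if (is.null(names(prediction_sets)) ||
        any(!nzchar(names(prediction_sets)))) {
    stop("prediction_sets must be a named list", call. = FALSE)
  }
  if (length(prediction_sets) < 2) {
    stop("agreement_partition needs at least two prediction sets",
         call. = FALSE)
  }
  ref_contigs <- unique(references$contig)
  labels <- names(prediction_sets)
  outcome_tbl <- purrr::imap_dfr(prediction_sets, function(pred, label) {
    extra <- setdiff(unique(pred$contig), ref_contigs)
    if (length(extra) > 0) {
      warning("pipeline ", label, " has contig(s) absent from the ",
              "reference: ", paste(extra, collapse = ", "), call. = FALSE)
    }
    cl <- classify_genes(pred, references, thresholds)
    ob <- outcome_by_reference(cl)
    tibble::tibble(pipeline = label, reference_id = ob$reference_id,
                   outcome = ob$outcome)
  })
  total <- nrow(gene_spans(references))

  subset_counts <- function(pred_match) {
    # pred_match: tibble reference_id, pipeline for the genes "in" the class
    cells <- pred_match |>
      dplyr::group_by(.data$reference_id) |>
      dplyr::summarise(
        pipelines = paste(labels[sort(match(.data$pipeline, labels))],
                          collapse = "+"),
        n_pipelines = dplyr::n(), .groups = "drop") |>
      dplyr::count(.data$pipelines, .data$n_pipelines, name = "n") |>
      dplyr::mutate(per_1000 = 1000 * .data$n / total) |>
      dplyr::arrange(dplyr::desc(.data$n_pipelines), .data$pipelines)
    cells
  }

  match_cells <- subset_counts(
    outcome_tbl[outcome_tbl$outcome %in% c("exact", "inexact"), ])
  cells <- dplyr::bind_rows(
    dplyr::mutate(match_cells, category = "match"),
    purrr::map_dfr(c("merged", "fragmented", "missing"), function(oc) {
      dplyr::mutate(subset_counts(outcome_tbl[outcome_tbl$outcome == oc, ]),
                    category = oc)
    })
  ) |>
    dplyr::select("category", "pipelines", "n_pipelines", "n", "per_1000")

  structure(list(
    cells = cells,
    n_unmatched = total - sum(match_cells$n),
    total_reference_genes = total,
    outcomes = outcome_tbl
  ), class = "agreement_partition")
}

#' @export
print.agreement_partition <- function(x, ...) {
  cat(sprintf(paste0("<agreement_partition> %d reference gene(s); %d ",
                     "matched by no pipeline\n"),
              x$total_reference_genes, x$n_unmatched))
  print(x$cells)
  invisible(x)
}

#' Consolidated evaluation of a prediction set against a reference
#'
#' Classifies every reference gene, tallies transcripts, exons (with
#' position breakdown) and introns over the classified groups, computes
#' accuracy statistics at all four stringencies, and derives a per-gene
#' F1 score (nucleotide stringency: the gene's CDS footprint against the
#' footprint of the predictions classified to it; 0 for missing genes)
#' suitable for ECDF comparison with [dts_test()].
#'
#' @param predictions,references [as_annotation()] tibbles.
#' @param gold_standard Optional [build_gold_standard()] tibble (or a
#'   character vector of gene ids): evaluation is then restricted to the
#'   member reference genes, exactly as if the reference had been
#'   pre-filtered to them.
#' @param thresholds A [classifier_thresholds()] list.
#' @return A list of class `annotation_report`: `classification`,
#'   `gene_outcomes` (count + fraction per outcome), `tally`,
#'   `exon_positions`, `accuracy`, `per_gene_f1`, and a `summary` list.
#' @export
evaluate_report <- function(predictions, references, gold_standard = NULL,
                            thresholds = classifier_thresholds()) {
  if (!is.null(gold_standard)) {
    ids <- if (is.data.frame(gold_standard)) {
      gold_standard$gene_id
    } else {
      as.character(gold_standard)
    }
    keep <- unique(references$gene_id) %in% ids
    if (!any(keep)) {
      stop("evaluate_report: no reference gene belongs to the gold standard",
           call. = FALSE)
    }
    references <- as_annotation(
      tibble::as_tibble(references)[references$gene_id %in% ids, ],
      source_label = attr(references, "source_label"))
  }
  classification <- classify_genes(predictions, references, thresholds)

  ref_levels <- c("exact", "inexact", "missing", "merged", "fragmented")
  per_ref <- outcome_by_reference(classification)
  gene_outcomes <- per_ref |>
    dplyr::count(outcome = factor(.data$outcome, levels = ref_levels),
                 name = "n", .drop = FALSE) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  n_unassigned <- sum(classification$outcome == "unassigned_prediction")

  tallies <- aggregate_tallies(classification, predictions, references)
  acc <- accuracy_stats(
    restrict_to_classified(predictions, classification), references)
  f1 <- per_gene_f1(classification, predictions, references)

  structure(list(
    classification = classification,
    gene_outcomes = gene_outcomes,
    n_unassigned_predictions = n_unassigned,
    tally = tallies$tally,
    exon_positions = tallies$exon_positions,
    accuracy = acc,
    per_gene_f1 = f1,
    summary = list(
      source = attr(predictions, "source_label") %||% "predictions",
      reference = attr(references, "source_label") %||% "references",
      total_reference_genes = sum(gene_outcomes$n),
      total_prediction_genes = nrow(gene_spans(predictions)),
      n_unassigned_predictions = n_unassigned,
      restricted = !is.null(gold_standard),
      thresholds = unclass(thresholds)
    )
  ), class = "annotation_report")
}

# predictions consumed by some classification (unassigned predictions are
# excluded from whole-set accuracy statistics against a possibly
# restricted reference)
restrict_to_classified <- function(predictions, classification) {
  keep_ids <- unlist(
    classification$prediction_ids[classification$outcome !=
                                    "unassigned_prediction"],
    use.names = FALSE)
  as_annotation(
    tibble::as_tibble(predictions)[predictions$gene_id %in% keep_ids, ],
    source_label = attr(predictions, "source_label"), validate = FALSE)
}

aggregate_tallies <- function(classification, predictions, references) {
  pred_tbl <- tibble::as_tibble(predictions)
  ref_tbl <- tibble::as_tibble(references)
  tally_sum <- NULL
  pos_sum <- NULL
  for (i in seq_len(nrow(classification))) {
    refs <- classification$reference_ids[[i]]
    preds <- classification$prediction_ids[[i]]
    p_ann <- pred_tbl[pred_tbl$gene_id %in% preds, , drop = FALSE]
    r_ann <- ref_tbl[ref_tbl$gene_id %in% refs, , drop = FALSE]
    if (nrow(p_ann) == 0 && nrow(r_ann) == 0) next
    asg <- if (nrow(p_ann) > 0 || nrow(r_ann) > 0) {
      match_transcripts(p_ann, r_ann)
    }
    ft <- tally_subfeatures(asg, p_ann, r_ann)
    if (is.null(tally_sum)) {
      tally_sum <- ft$tally
      pos_sum <- ft$exon_positions
    } else {
      num <- c("matched", "missing", "false_positive", "exact")
      tally_sum[num] <- tally_sum[num] + ft$tally[num]
      num2 <- c("matched", "missing", "false_positive")
      pos_sum[num2] <- pos_sum[num2] + ft$exon_positions[num2]
    }
  }
  if (is.null(tally_sum)) {
    tally_sum <- tibble::tibble(level = c("transcript", "exon", "intron"),
                                matched = 0L, missing = 0L,
                                false_positive = 0L, exact = 0L)
    pos_sum <- tibble::tibble(
      position_class = c("initial", "internal", "terminal", "single"),
      matched = 0L, missing = 0L, false_positive = 0L)
  }
  list(tally = tally_sum, exon_positions = pos_sum)
}

#' Per-reference-gene F1 scores
#'
#' For each classified reference gene, the nucleotide-level F1 of its CDS
#' footprint against the pooled CDS footprint of the prediction gene(s)
#' classified with it. Missing genes score 0.
#'
#' @param classification Output of [classify_genes()].
#' @param predictions,references The annotation tibbles that were
#'   classified.
#' @return A tibble: `reference_id`, `outcome`, `F1`.
#' @export
per_gene_f1 <- function(classification, predictions, references) {
  pred_tbl <- tibble::as_tibble(predictions)
  ref_tbl <- tibble::as_tibble(references)
  per_ref <- outcome_by_reference(classification)
  f1 <- vapply(seq_len(nrow(per_ref)), function(i) {
    r <- per_ref$reference_id[i]
    preds <- per_ref$prediction_ids[[i]]
    if (length(preds) == 0) return(0)
    cc <- confusion_counts(
      as_annotation(pred_tbl[pred_tbl$gene_id %in% preds, ],
                    validate = FALSE),
      as_annotation(ref_tbl[ref_tbl$gene_id == r, ], validate = FALSE),
      level = "nucleotide")
    sn_pr_f1(cc)$F1
  }, numeric(1))
  tibble::tibble(reference_id = per_ref$reference_id,
                 outcome = per_ref$outcome, F1 = f1)
}

#' @export
print.annotation_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<annotation_report> %s vs %s\n", s$source, s$reference))
  cat(sprintf("  %d reference gene(s), %d prediction gene(s), %d unassigned\n",
              s$total_reference_genes, s$total_prediction_genes,
              s$n_unassigned_predictions))
  cat("\nGene outcomes:\n")
  print(x$gene_outcomes)
  cat("\nAccuracy:\n")
  print(x$accuracy)
  invisible(x)
}

#' @rdname evaluate_report
#' @param x An `annotation_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.annotation_report <- function(x, ...) {
  wide <- stats::setNames(as.list(x$gene_outcomes$n),
                          paste0("n_", x$gene_outcomes$outcome))
  f1 <- x$accuracy$F1[x$accuracy$level == "nucleotide"]
  tibble::as_tibble(c(
    list(total_reference_genes = x$summary$total_reference_genes,
         total_prediction_genes = x$summary$total_prediction_genes),
    wide,
    list(n_unassigned_predictions = x$summary$n_unassigned_predictions,
         nucleotide_F1 = f1,
         mean_per_gene_F1 = mean(x$per_gene_f1$F1))
  ))
}

#' Write an evaluation report to disk
#'
#' Emits `gene_classification.tsv`, `feature_tally.tsv`,
#' `exon_positions.tsv`, `accuracy.tsv`, `per_gene_f1.tsv` and
#' `summary.json` under `dir`. Every TSV starts with a provenance comment
#' line (package version and thresholds) and a header row.
#'
#' @param report An [evaluate_report()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- sprintf(
    "# annoclass %s | thresholds: merged_ref_coverage=%g, fragment_pred_coverage=%g, fragment_mutual_overlap_max=%g",
    as.character(utils::packageVersion("annoclass")),
    report$summary$thresholds$merged_ref_coverage,
    report$summary$thresholds$fragment_pred_coverage,
    report$summary$thresholds$fragment_mutual_overlap_max)
  write_tsv_prov <- function(tbl, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(prov, con)
    utils::write.table(tbl, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  cl <- report$classification
  cl_flat <- tibble::tibble(
    outcome = as.character(cl$outcome),
    reference_ids = vapply(cl$reference_ids, paste, "", collapse = ","),
    prediction_ids = vapply(cl$prediction_ids, paste, "", collapse = ","),
    contig = cl$contig, strand = cl$strand,
    coverages = vapply(cl$coverages, function(cc) {
      paste(sprintf("%s:%s=%.4f", cc$prediction_id, cc$reference_id,
                    cc$ref_coverage), collapse = ";")
    }, "")
  )
  paths <- c(
    write_tsv_prov(cl_flat, file.path(dir, "gene_classification.tsv")),
    write_tsv_prov(report$tally, file.path(dir, "feature_tally.tsv")),
    write_tsv_prov(report$exon_positions,
                   file.path(dir, "exon_positions.tsv")),
    write_tsv_prov(report$accuracy, file.path(dir, "accuracy.tsv")),
    write_tsv_prov(report$per_gene_f1[, c("reference_id", "outcome", "F1")],
                   file.path(dir, "per_gene_f1.tsv"))
  )
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(
    c(report$summary,
      list(gene_outcomes = report$gene_outcomes,
           accuracy = report$accuracy)),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, summary_path))
}
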