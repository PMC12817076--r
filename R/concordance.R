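# Evidence-concordance gene selection: keep gene structures agreed by at
# least `min_agree` of the given evidence sources. Used to pick reliable
# gene models (e.g. for gene-predictor training) from transcript-derived
# ORFs, protein alignments and ab initio predictions.

#' Select gene models concordant across evidence sources
#'
#' Two gene models are concordant when they have identical
#' (contig, strand, ordered CDS segment coordinate chain) — for
#' multi-transcript genes, the full sorted set of transcript chains. Each
#' equivalence class of identical structures supported by at least
#' `min_agree` distinct sources contributes one representative, taken from
#' the earliest supporting source in argument order (ids included).
#'
#' @param source_a,source_b,source_c [as_annotation()] tibbles from three
#'   independent evidence sources on the same contigs.
#' @param min_agree Minimum number of distinct supporting sources
#'   (default 2; must be between 1 and 3).
#' @return An [as_annotation()] tibble of representatives, sorted; the
#'   attribute `"provenance"` is a tibble (`gene_id`, `n_sources`,
#'   `sources`) recording which sources supported each selected model.
#' @export
select_concordant <- function(source_a, source_b, source_c, min_agree = 2L) {
  if (min_agree < 1 || min_agree > 3) {
    stop("min_agree must be between 1 and 3", call. = FALSE)
  }
  sources <- list(a = source_a, b = source_b, c = source_c)
  labels <- vapply(seq_along(sources), function(i) {
    attr(sources[[i]], "source_label") %||% names(sources)[i]
  }, character(1))
  if (anyDuplicated(labels)) labels <- names(sources)

  keys <- lapply(sources, gene_structure_keys)
  all_keys <- unique(unlist(lapply(keys, function(k) k$key),
                            use.names = FALSE))
  support <- sapply(keys, function(k) all_keys %in% k$key)
  if (is.null(dim(support))) support <- matrix(support, nrow = 1)
  n_support <- rowSums(support)
  selected <- all_keys[n_support >= min_agree]

  if (length(selected) == 0) {
    out <- as_annotation(tibble::tibble(
      contig = character(), strand = character(), gene_id = character(),
      transcript_id = character(), start = integer(), end = integer()
    ), source_label = "concordant")
    attr(out, "provenance") <- tibble::tibble(
      gene_id = character(), n_sources = integer(), sources = list())
    return(out)
  }

  rows <- list()
  prov <- list()
  for (key in selected) {
    src_idx <- which(support[match(key, all_keys), ])
    first <- src_idx[1]
    gid <- keys[[first]]$gene_id[match(key, keys[[first]]$key)]
    ann <- sources[[first]]
    rows[[length(rows) + 1L]] <-
      tibble::as_tibble(ann)[ann$gene_id == gid, ]
    prov[[length(prov) + 1L]] <- tibble::tibble(
      gene_id = gid, n_sources = length(src_idx),
      sources = list(labels[src_idx]))
  }
  out <- as_annotation(dplyr::bind_rows(rows), source_label = "concordant")
  attr(out, "provenance") <- dplyr::bind_rows(prov)
  out
}

# one structure key per gene: contig|strand|sorted transcript chains
gene_structure_keys <- function(ann) {
  if (nrow(ann) == 0) {
    return(tibble::tibble(gene_id = character(), key = character()))
  }
  tibble::as_tibble(ann) |>
    dplyr::arrange(.data$transcript_id, .data$start) |>
    dplyr::group_by(.data$gene_id, .data$transcript_id) |>
    dplyr::summarise(
      contig = .data$contig[1], strand = .data$strand[1],
      chain = paste(.data$start, .data$end, sep = "-", collapse = ","),
      .groups = "drop_last") |>
    dplyr::summarise(
      key = paste(.data$contig[1], .data$strand[1],
                  paste(sort(.data$chain), collapse = ";"), sep = "|"),
      .groups = "drop")
}
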