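# Core container: an annotation is a tibble of CDS segments, one row per
# segment per transcript, with 1-based inclusive coordinates.

#' Build an annotation set from a data frame of CDS segments
#'
#' An *annotation* is the package's central container: a tibble with one row
#' per CDS segment per transcript and columns `contig`, `strand` (`"+"` or
#' `"-"`), `gene_id`, `transcript_id`, `start`, `end` (1-based, inclusive)
#' and optionally `phase` (0, 1, 2 or `NA`). Gene spans, introns and exon
#' position classes are derived from these rows; UTRs are never modelled, so
#' a gene's extent is the extent of its coding segments.
#'
#' @param x A data frame with at least the columns listed above.
#' @param source_label Free-text label identifying the annotation source
#'   (e.g. a pipeline name); stored as an attribute and used in reports.
#' @param validate If `TRUE` (default), check structural invariants:
#'   positive, ordered coordinates; segments of one transcript on a single
#'   contig and strand, pairwise non-overlapping; all transcripts of a gene
#'   on one contig and strand; gene ids not reused across contigs or strands.
#' @return A tibble of class `annotation`, rows sorted by
#'   (contig, gene start, gene id, transcript id, segment start).
#' @examples
#' ann <- as_annotation(data.frame(
#'   contig = "chr1", strand = "+", gene_id = "g1", transcript_id = "t1",
#'   start = c(101, 301), end = c(200, 420)
#' ))
#' gene_spans(ann)
#' @seealso [read_gff3()], [gene_spans()], [derive_introns()]
#' @export
as_annotation <- function(x, source_label = NULL, validate = TRUE) {
  required <- c("contig", "strand", "gene_id", "transcript_id", "start", "end")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(x)
  if (!"phase" %in% names(out)) out$phase <- NA_integer_
  out$contig <- as.character(out$contig)
  out$strand <- as.character(out$strand)
  out$gene_id <- as.character(out$gene_id)
  out$transcript_id <- as.character(out$transcript_id)
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out$phase <- as.integer(out$phase)
  if (validate && nrow(out) > 0) validate_annotation(out)
  out <- sort_annotation(out)
  attr(out, "source_label") <-
    source_label %||% attr(x, "source_label", exact = TRUE) %||% "annotation"
  class(out) <- unique(c("annotation", class(out)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> %s: %d gene(s), %d transcript(s), %d CDS segment(s)\n",
              attr(x, "source_label") %||% "annotation",
              length(unique(x$gene_id)), length(unique(x$transcript_id)), nrow(x)))
  NextMethod()
}

sort_annotation <- function(x) {
  if (nrow(x) == 0) return(x)
  gs <- stats::aggregate(start ~ gene_id, data = x, FUN = min)
  gstart <- stats::setNames(gs$start, gs$gene_id)
  ord <- order(x$contig, gstart[x$gene_id], x$gene_id, x$transcript_id, x$start)
  x[ord, , drop = FALSE]
}

validate_annotation <- function(x) {
  bad <- which(x$start < 1L | x$end < x$start | is.na(x$start) | is.na(x$end))
  if (length(bad) > 0) {
    stop("invalid CDS coordinates (need 1 <= start <= end) for transcript(s): ",
         paste(unique(x$transcript_id[bad]), collapse = ", "), call. = FALSE)
  }
  if (!all(x$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  by_tx <- split(seq_len(nrow(x)), x$transcript_id)
  for (idx in by_tx) {
    if (length(unique(x$contig[idx])) > 1 || length(unique(x$strand[idx])) > 1) {
      stop("transcript ", x$transcript_id[idx[1]],
           " has segments on multiple contigs or strands", call. = FALSE)
    }
    if (length(unique(x$gene_id[idx])) > 1) {
      stop("transcript ", x$transcript_id[idx[1]],
           " is attached to multiple genes", call. = FALSE)
    }
    o <- idx[order(x$start[idx])]
    if (length(o) > 1 && any(x$start[o][-1] <= x$end[o][-length(o)])) {
      stop("transcript ", x$transcript_id[idx[1]],
           " has overlapping CDS segments", call. = FALSE)
    }
  }
  gtab <- unique(x[, c("gene_id", "contig", "strand")])
  if (anyDuplicated(gtab$gene_id)) {
    dup <- gtab$gene_id[duplicated(gtab$gene_id)]
    stop("gene id(s) reused across contigs or strands: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Per-gene coding spans
#'
#' The span of a gene is the interval from the smallest CDS start to the
#' largest CDS end over all of its transcripts. Spans drive the gene-level
#' outcome classification.
#'
#' @param annotation An [as_annotation()] tibble.
#' @return A tibble with one row per gene: `gene_id`, `contig`, `strand`,
#'   `start`, `end`, `length`, `n_transcripts`, sorted by (contig, start,
#'   gene_id).
#' @export
gene_spans <- function(annotation) {
  if (nrow(annotation) == 0) {
    return(tibble::tibble(gene_id = character(), contig = character(),
                          strand = character(), start = integer(),
                          end = integer(), length = integer(),
                          n_transcripts = integer()))
  }
  annotation |>
    dplyr::group_by(.data$gene_id, .data$contig, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     n_transcripts = dplyr::n_distinct(.data$transcript_id),
                     .groups = "drop") |>
    dplyr::mutate(length = .data$end - .data$start + 1L) |>
    dplyr::select("gene_id", "contig", "strand", "start", "end",
                  "length", "n_transcripts") |>
    dplyr::arrange(.data$contig, .data$start, .data$gene_id)
}

#' Per-transcript coding spans and lengths
#'
#' @param annotation An [as_annotation()] tibble.
#' @return A tibble with one row per transcript: ids, contig, strand, span
#'   `start`/`end`, `coding_length` (sum of segment lengths) and `n_segments`.
#' @export
transcript_spans <- function(annotation) {
  annotation |>
    dplyr::group_by(.data$gene_id, .data$transcript_id,
                    .data$contig, .data$strand) |>
    dplyr::summarise(coding_length = sum(.data$end - .data$start + 1L),
                     n_segments = dplyr::n(),
                     start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::select("gene_id", "transcript_id", "contig", "strand",
                  "start", "end", "coding_length", "n_segments") |>
    dplyr::arrange(.data$contig, .data$start, .data$transcript_id)
}

#' Derive intron coordinates from CDS chains
#'
#' An intron is the gap between two consecutive CDS segments of one
#' transcript: for consecutive segments a, b the intron is
#' `[a$end + 1, b$start - 1]`, emitted only when the gap holds at least
#' `min_intron_length` nucleotides. Directly adjacent segments (gap 0)
#' produce no intron, since a splice junction needs a gap.
#'
#' @param annotation An [as_annotation()] tibble.
#' @param min_intron_length Minimum gap width, in nucleotides, to call an
#'   intron (default 1).
#' @return A tibble of introns: `contig`, `strand`, `gene_id`,
#'   `transcript_id`, `start`, `end`, sorted within each transcript.
#' @examples
#' ann <- as_annotation(data.frame(
#'   contig = "c", strand = "+", gene_id = "g", transcript_id = "t",
#'   start = c(100, 300), end = c(200, 400)
#' ))
#' derive_introns(ann)  # one intron [201, 299]
#' @export
derive_introns <- function(annotation, min_intron_length = 1L) {
  if (nrow(annotation) == 0) {
    return(tibble::tibble(contig = character(), strand = character(),
                          gene_id = character(), transcript_id = character(),
                          start = integer(), end = integer()))
  }
  annotation |>
    dplyr::arrange(.data$transcript_id, .data$start) |>
    dplyr::group_by(.data$contig, .data$strand, .data$gene_id,
                    .data$transcript_id) |>
    dplyr::reframe(intron_start = .data$end[-dplyr::n()] + 1L,
                   intron_end = .data$start[-1L] - 1L) |>
    dplyr::rename(start = "intron_start", end = "intron_end") |>
    dplyr::filter(.data$end - .data$start + 1L >= min_intron_length) |>
    dplyr::arrange(.data$contig, .data$transcript_id, .data$start)
}

#' Classify CDS segments by position within their transcript
#'
#' Coding exons are classed as `single` (only segment of the transcript),
#' `initial` (5'-most segment in transcription direction), `terminal`
#' (3'-most) or `internal`. On the minus strand the initial segment is the
#' one with the largest genomic start.
#'
#' @param annotation An [as_annotation()] tibble.
#' @return The annotation with an added `position_class` column.
#' @export
cds_position_class <- function(annotation) {
  if (nrow(annotation) == 0) {
    annotation$position_class <- character()
    return(annotation)
  }
  annotation |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::mutate(position_class = {
      n <- dplyr::n()
      rk <- rank(.data$start, ties.method = "first")
      if (n == 1L) {
        "single"
      } else {
        five <- if (.data$strand[1] == "+") rk == 1L else rk == n
        three <- if (.data$strand[1] == "+") rk == n else rk == 1L
        dplyr::case_when(five ~ "initial", three ~ "terminal",
                         TRUE ~ "internal")
      }
    }) |>
    dplyr::ungroup()
}
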