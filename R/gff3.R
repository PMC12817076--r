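# GFF3 input/output for the gene -> mRNA -> CDS hierarchy.
# External coordinates are 1-based inclusive per the GFF3 standard; the
# annotation tibble keeps the same convention, so no conversion happens here.

#' Read a GFF3 gene annotation
#'
#' Parses the gene / mRNA / CDS hierarchy of a GFF3 file into an
#' [as_annotation()] tibble. Only coding structure is retained: feature
#' types other than `gene`, `mRNA`/`transcript` and `CDS` are ignored, as
#' are genes without any transcript carrying at least one CDS segment.
#' A CDS row listing several parents (`Parent=t1,t2`) is attached to each
#' listed transcript. Malformed rows (wrong column count, `end < start`,
#' unknown parents, duplicate gene ids, invalid strand) raise errors that
#' name the offending line.
#'
#' @param file Path to a GFF3 file, or a character vector of GFF3 lines.
#' @param source_label Label stored on the result; defaults to the file name.
#' @param lenient If `TRUE`, features on strand `"."` (or `"?"`) are skipped
#'   with a warning instead of raising an error. The downstream classifier
#'   is strand-aware, so unstranded features can never match anything.
#' @return An [as_annotation()] tibble.
#' @export
read_gff3 <- function(file, source_label = NULL, lenient = FALSE) {
  if (length(file) == 1 && !grepl("\t|\n", file)) {
    if (!file.exists(file)) {
      stop("read_gff3: file not found: '", file, "'", call. = FALSE)
    }
    lines <- readLines(file, warn = FALSE)
    source_label <- source_label %||% basename(file)
  } else {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
    source_label <- source_label %||% "gff3"
  }
  fasta_at <- which(lines == "##FASTA")
  if (length(fasta_at) > 0) lines <- lines[seq_len(fasta_at[1] - 1L)]
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)

  nfield <- lengths(rows)
  if (any(nfield != 9L)) {
    bad <- lineno[which(nfield != 9L)[1]]
    stop("GFF3 line ", bad, ": expected 9 tab-separated columns, found ",
         nfield[which(nfield != 9L)[1]], call. = FALSE)
  }
  if (length(rows) == 0) {
    return(as_annotation(tibble::tibble(
      contig = character(), strand = character(), gene_id = character(),
      transcript_id = character(), start = integer(), end = integer()
    ), source_label = source_label))
  }
  m <- matrix(unlist(rows, use.names = FALSE), ncol = 9L, byrow = TRUE)
  type <- m[, 3]
  sel <- type %in% c("gene", "mRNA", "transcript", "CDS")
  m <- m[sel, , drop = FALSE]
  lineno <- lineno[sel]
  type <- type[sel]
  type[type == "transcript"] <- "mRNA"

  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | start < 1L | end < start)
  if (length(bad) > 0) {
    stop("GFF3 line ", lineno[bad[1]], ": invalid coordinates (start=",
         m[bad[1], 4], ", end=", m[bad[1], 5], ")", call. = FALSE)
  }
  strand <- m[, 7]
  unstranded <- which(!strand %in% c("+", "-"))
  if (length(unstranded) > 0) {
    if (!lenient) {
      stop("GFF3 line ", lineno[unstranded[1]], ": feature on strand '",
           strand[unstranded[1]],
           "'; only '+' and '-' are supported (use lenient = TRUE to skip)",
           call. = FALSE)
    }
    warning("skipped ", length(unstranded),
            " feature(s) without a '+'/'-' strand", call. = FALSE)
    keep2 <- setdiff(seq_len(nrow(m)), unstranded)
    m <- m[keep2, , drop = FALSE]; lineno <- lineno[keep2]
    type <- type[keep2]; start <- start[keep2]; end <- end[keep2]
    strand <- strand[keep2]
  }

  attr_field <- m[, 9]
  ids <- gff3_attr(attr_field, "ID")
  parents <- gff3_attr(attr_field, "Parent")
  phase <- suppressWarnings(as.integer(m[, 8]))

  is_gene <- type == "gene"
  gene_ids <- ids[is_gene]
  if (anyNA(gene_ids)) {
    stop("GFF3 line ", lineno[is_gene][which(is.na(gene_ids))[1]],
         ": gene row without an ID attribute", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    dup <- which(duplicated(gene_ids))[1]
    stop("GFF3 line ", lineno[is_gene][dup], ": duplicate gene ID '",
         gene_ids[dup], "'", call. = FALSE)
  }
  gene_set <- gene_ids

  is_tx <- type == "mRNA"
  tx_ids <- ids[is_tx]
  tx_parent <- parents[is_tx]
  if (anyNA(tx_ids)) {
    stop("GFF3 line ", lineno[is_tx][which(is.na(tx_ids))[1]],
         ": mRNA row without an ID attribute", call. = FALSE)
  }
  bad_tx <- which(is.na(tx_parent) | !tx_parent %in% gene_set)
  if (length(bad_tx) > 0) {
    stop("GFF3 line ", lineno[is_tx][bad_tx[1]], ": mRNA '",
         tx_ids[bad_tx[1]], "' has unknown gene parent '",
         tx_parent[bad_tx[1]], "'", call. = FALSE)
  }
  tx2gene <- stats::setNames(tx_parent, tx_ids)

  is_cds <- type == "CDS"
  cds_parents <- strsplit(parents[is_cds], ",", fixed = TRUE)
  cds_line <- lineno[is_cds]
  na_parent <- which(is.na(parents[is_cds]))
  if (length(na_parent) > 0) {
    stop("GFF3 line ", cds_line[na_parent[1]],
         ": CDS row without a Parent attribute", call. = FALSE)
  }
  reps <- lengths(cds_parents)
  cds_tx <- as.character(unlist(cds_parents, use.names = FALSE))
  unknown <- which(!cds_tx %in% names(tx2gene))
  if (length(unknown) > 0) {
    stop("GFF3 line ", rep(cds_line, reps)[unknown[1]],
         ": CDS has unknown transcript parent '", cds_tx[unknown[1]], "'",
         call. = FALSE)
  }
  out <- tibble::tibble(
    contig = rep(m[is_cds, 1], reps),
    strand = rep(strand[is_cds], reps),
    gene_id = unname(tx2gene[cds_tx]),
    transcript_id = cds_tx,
    start = rep(start[is_cds], reps),
    end = rep(end[is_cds], reps),
    phase = rep(phase[is_cds], reps)
  )
  as_annotation(out, source_label = source_label)
}

gff3_attr <- function(attrs, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]+)")
  hits <- regmatches(attrs, regexec(pat, attrs, perl = TRUE))
  vapply(hits, function(g) if (length(g) >= 2) g[2] else NA_character_,
         character(1))
}

#' Write an annotation as GFF3
#'
#' Emits gene, mRNA and CDS rows, 1-based inclusive, deterministically
#' ordered by (contig, gene span start, gene id). `read_gff3(write_gff3(x))`
#' is structurally identical to `x`.
#'
#' @param annotation An [as_annotation()] tibble.
#' @param file Optional path; when `NULL` the GFF3 text is returned as a
#'   character vector of lines.
#' @param source Value for the GFF3 source column (default `"annoclass"`).
#' @return Invisibly (when writing to a file) or visibly (otherwise), the
#'   GFF3 lines.
#' @export
write_gff3 <- function(annotation, file = NULL, source = "annoclass") {
  lines <- "##gff-version 3"
  if (nrow(annotation) > 0) {
    ann <- sort_annotation(tibble::as_tibble(annotation))
    gs <- gene_spans(ann)
    ts <- transcript_spans(ann)
    ts <- ts[order(match(ts$gene_id, gs$gene_id), ts$start, ts$transcript_id), ]
    gene_rows <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                         gs$contig, source, gs$start, gs$end, gs$strand,
                         gs$gene_id)
    tx_rows <- sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       ts$contig, source, ts$start, ts$end, ts$strand,
                       ts$transcript_id, ts$gene_id)
    cds <- ann[order(match(ann$transcript_id, ts$transcript_id), ann$start), ]
    cds_rows <- sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%s\tParent=%s",
                        cds$contig, source, cds$start, cds$end, cds$strand,
                        ifelse(is.na(cds$phase), ".", as.character(cds$phase)),
                        cds$transcript_id)
    # interleave: gene row, then its mRNA rows each followed by its CDS rows
    tx_by_gene <- split(seq_len(nrow(ts)), ts$gene_id)
    cds_by_tx <- split(cds_rows, cds$transcript_id)
    out <- vector("list", nrow(gs))
    for (i in seq_len(nrow(gs))) {
      g <- gs$gene_id[i]
      txi <- tx_by_gene[[g]]
      tx_blocks <- unlist(lapply(txi, function(j) {
        c(tx_rows[j], cds_by_tx[[ts$transcript_id[j]]])
      }), use.names = FALSE)
      out[[i]] <- c(gene_rows[i], tx_blocks)
    }
    lines <- c(lines, unlist(out, use.names = FALSE))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Read a plain-text gene identifier list
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored; leading/trailing whitespace is trimmed.
#'
#' @param file Path to the list, or a character vector of lines.
#' @return A character vector of unique identifiers.
#' @export
read_id_list <- function(file) {
  if (length(file) == 1 && !grepl("\n", file) && !file.exists(file)) {
    stop("read_id_list: file not found: '", file, "'", call. = FALSE)
  }
  lines <- if (length(file) == 1 && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- trimws(lines)
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}
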