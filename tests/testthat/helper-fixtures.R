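# Fixture builders and independent brute-force oracles used across the
# suite. Oracles deliberately share no code with the implementation paths
# they check.

# Compact annotation builder: genes given as list(gene_id = list(t1 =
# "100-200,300-400", ...)) on one contig/strand unless overridden.
mk_ann <- function(genes, contig = "c1", strand = "+", label = "fixture") {
  rows <- list()
  for (g in names(genes)) {
    txs <- genes[[g]]
    if (is.character(txs)) txs <- stats::setNames(list(txs), paste0(g, ".t1"))
    for (tx in names(txs)) {
      segs <- strsplit(strsplit(txs[[tx]], ",", fixed = TRUE)[[1]], "-")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        contig = contig, strand = strand, gene_id = g, transcript_id = tx,
        start = as.integer(vapply(segs, `[`, "", 1)),
        end = as.integer(vapply(segs, `[`, "", 2))
      )
    }
  }
  as_annotation(dplyr::bind_rows(rows), source_label = label)
}

gff_field <- function(lines, i) {
  vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", i)
}

# structural equality of two annotations, ignoring attributes and order
expect_ann_equal <- function(a, b) {
  cols <- c("contig", "strand", "gene_id", "transcript_id", "start", "end")
  norm <- function(x) {
    df <- as.data.frame(x)[cols]
    df <- df[do.call(order, df), ]
    rownames(df) <- NULL
    df
  }
  expect_equal(norm(a), norm(b))
}

# Oracle: optimal one-to-one assignment by exhaustive enumeration over all
# injective pairings (both directions), returning the maximum total weight.
brute_force_assignment_value <- function(weights) {
  weights <- weights[weights$weight > 0, , drop = FALSE]
  if (nrow(weights) == 0) return(0)
  rows <- unique(weights$row)
  cols <- unique(weights$col)
  wm <- matrix(0, length(rows), length(cols),
               dimnames = list(rows, cols))
  wm[cbind(match(weights$row, rows), match(weights$col, cols))] <-
    weights$weight
  best <- 0
  recurse <- function(i, used, acc) {
    if (i > length(rows)) {
      best <<- max(best, acc)
      return()
    }
    recurse(i + 1L, used, acc)  # leave row i unmatched
    for (j in seq_along(cols)) {
      if (!used[j] && wm[i, j] > 0) {
        used[j] <- TRUE
        recurse(i + 1L, used, acc + wm[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, length(cols)), 0)
  best
}

# Oracle: nucleotide confusion by literal per-base bitmaps per
# (contig, strand).
bitmap_confusion <- function(pred, ref, max_pos = 20000L) {
  keys <- unique(rbind(unique(as.data.frame(pred)[c("contig", "strand")]),
                       unique(as.data.frame(ref)[c("contig", "strand")])))
  tp <- fp <- fn <- 0L
  for (i in seq_len(nrow(keys))) {
    p <- ref_mask <- pred_mask <- logical(max_pos)
    sel_p <- pred$contig == keys$contig[i] & pred$strand == keys$strand[i]
    sel_r <- ref$contig == keys$contig[i] & ref$strand == keys$strand[i]
    for (k in which(sel_p)) pred_mask[pred$start[k]:pred$end[k]] <- TRUE
    for (k in which(sel_r)) ref_mask[ref$start[k]:ref$end[k]] <- TRUE
    tp <- tp + sum(pred_mask & ref_mask)
    fp <- fp + sum(pred_mask & !ref_mask)
    fn <- fn + sum(!pred_mask & ref_mask)
  }
  c(TP = tp, FP = fp, FN = fn)
}

# Oracle: DTS statistic evaluated term by term from its definition using
# explicit ECDF functions (no shared code with dts_statistic).
brute_dts <- function(a, b) {
  fa <- stats::ecdf(a); fb <- stats::ecdf(b); fh <- stats::ecdf(c(a, b))
  x <- sort(c(a, b))
  total <- 0
  for (k in seq_len(length(x) - 1)) {
    h <- fh(x[k])
    if (h > 0 && h < 1) {
      total <- total + abs(fa(x[k]) - fb(x[k])) * (x[k + 1] - x[k]) /
        sqrt(h * (1 - h))
    }
  }
  total
}

# random annotation (possibly messy) for round-trip and confusion tests:
# genes laid out with small random gaps, random exon counts
random_annotation <- function(n_genes, seed, contig = "c1",
                              max_pos = 10000L, label = "rand") {
  withr::local_seed(seed)
  rows <- list()
  pos <- 1L
  for (i in seq_len(n_genes)) {
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(1:4, 1)
    pos <- pos + sample(20:120, 1)
    starts <- integer(n_ex); ends <- integer(n_ex)
    p <- pos
    for (e in seq_len(n_ex)) {
      len <- sample(30:200, 1)
      starts[e] <- p
      ends[e] <- p + len - 1L
      p <- ends[e] + sample(25:90, 1)
    }
    if (ends[n_ex] > max_pos) break
    gid <- sprintf("rg%03d", i)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      contig = contig, strand = strand, gene_id = gid,
      transcript_id = paste0(gid, ".t1"), start = starts, end = ends)
    pos <- ends[n_ex]
  }
  as_annotation(dplyr::bind_rows(rows), source_label = label)
}
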