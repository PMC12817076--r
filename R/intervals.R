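# Interval arithmetic and the exact maximum-weight bipartite assignment
# used for transcript and sub-feature matching.

#' Fraction of an interval covered by another
#'
#' Computes `overlap(a, b) / length(b)`: the fraction of interval `b`
#' covered by interval `a`. This is the quantity the merged/fragmented
#' rules threshold ("covered by more than half its length"). Vectorised;
#' intervals are 1-based inclusive.
#'
#' @param a,b Data frames (or lists) with `start` and `end` columns and
#'   optionally `contig`; rows are recycled to a common length.
#' @return A numeric vector in `[0, 1]`; 0 for disjoint intervals.
#' @examples
#' coverage_fraction(data.frame(start = 101, end = 200),
#'                   data.frame(start = 151, end = 250))  # 0.5
#' @export
coverage_fraction <- function(a, b) {
  if (!is.null(a$contig) && !is.null(b$contig) && any(a$contig != b$contig)) {
    stop("coverage_fraction: intervals on different contigs", call. = FALSE)
  }
  ov <- pmax(0L, pmin(a$end, b$end) - pmax(a$start, b$start) + 1L)
  ov / (b$end - b$start + 1)
}

# Overlap in nucleotides between two sets of sorted, disjoint segments
# (CDS footprints). Base-vectorised; segment counts are small.
footprint_overlap <- function(start_a, end_a, start_b, end_b) {
  if (length(start_a) == 0 || length(start_b) == 0) return(0L)
  lo <- outer(start_a, start_b, pmax)
  hi <- outer(end_a, end_b, pmin)
  sum(pmax(0L, hi - lo + 1L))
}

#' Maximum-weight one-to-one assignment
#'
#' Exact maximum-weight bipartite matching on a sparse weight table, used
#' to pair prediction with reference transcripts (and exons, introns) by
#' total nucleotide overlap. Pairs with non-positive weight are never
#' created. Among equally optimal assignments the one preferring, for each
#' row in `row_order`, the earliest column in `col_order` is returned, so
#' results are deterministic.
#'
#' Solved by dynamic programming over subsets of the smaller side; intended
#' for the small groups that share a gene locus (an error is raised beyond
#' 16 x 16).
#'
#' @param weights A data frame with columns `row`, `col`, `weight`
#'   (positive entries only are considered).
#' @param row_order,col_order Character vectors giving the full universe
#'   and preference order of row/column ids (e.g. by genomic start).
#' @return A tibble of `row`, `col`, `weight` pairs; attribute
#'   `total_weight` holds the optimum.
#' @export
max_weight_assignment <- function(weights,
                                  row_order = unique(weights$row),
                                  col_order = unique(weights$col)) {
  weights <- weights[weights$weight > 0, , drop = FALSE]
  empty <- tibble::tibble(row = character(), col = character(),
                          weight = numeric())
  attr(empty, "total_weight") <- 0
  if (nrow(weights) == 0) return(empty)
  rows <- intersect(row_order, unique(weights$row))
  cols <- intersect(col_order, unique(weights$col))
  if (length(cols) > 16) {
    if (length(rows) <= 16) {
      res <- max_weight_assignment(
        data.frame(row = weights$col, col = weights$row,
                   weight = weights$weight),
        row_order = col_order, col_order = row_order)
      out <- tibble::tibble(row = res$col, col = res$row, weight = res$weight)
      attr(out, "total_weight") <- attr(res, "total_weight")
      return(out)
    }
    stop("assignment group too large (more than 16 features per side)",
         call. = FALSE)
  }
  n <- length(rows); m <- length(cols)
  w <- matrix(0, n, m, dimnames = list(rows, cols))
  w[cbind(match(weights$row, rows), match(weights$col, cols))] <-
    weights$weight
  nmask <- bitwShiftL(1L, m)
  # best[i + 1][mask + 1]: optimum using rows i..n with columns in `mask`
  # already unavailable
  best <- matrix(0, n + 1L, nmask)
  for (i in n:1) {
    for (mask in 0:(nmask - 1L)) {
      v <- best[i + 1L, mask + 1L]  # leave row i unmatched
      for (j in seq_len(m)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (w[i, j] > 0 && bitwAnd(mask, bit) == 0L) {
          cand <- w[i, j] + best[i + 1L, bitwOr(mask, bit) + 1L]
          if (cand > v) v <- cand
        }
      }
      best[i, mask + 1L] <- v
    }
  }
  # Reconstruct: rows in order; prefer the earliest achievable column,
  # matching whenever a match attains the optimum.
  mask <- 0L
  pairs_row <- character(0); pairs_col <- character(0); pairs_w <- numeric(0)
  for (i in seq_len(n)) {
    target <- best[i, mask + 1L]
    chosen <- NA_integer_
    for (j in seq_len(m)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (w[i, j] > 0 && bitwAnd(mask, bit) == 0L &&
          isTRUE(all.equal(w[i, j] + best[i + 1L, bitwOr(mask, bit) + 1L],
                           target))) {
        chosen <- j
        break
      }
    }
    if (!is.na(chosen)) {
      pairs_row <- c(pairs_row, rows[i])
      pairs_col <- c(pairs_col, cols[chosen])
      pairs_w <- c(pairs_w, w[i, chosen])
      mask <- bitwOr(mask, bitwShiftL(1L, chosen - 1L))
    }
  }
  out <- tibble::tibble(row = pairs_row, col = pairs_col, weight = pairs_w)
  attr(out, "total_weight") <- best[1L, 1L]
  out
}
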