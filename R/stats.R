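# Burset–Guigó-style accuracy statistics, the variance-weighted two-sample
# ECDF statistic with its permutation test, and the two-proportion z-test.

#' Confusion counts between prediction and reference at a given stringency
#'
#' \describe{
#'   \item{nucleotide}{per-base coding membership on each (contig, strand):
#'     a base is a true positive when both annotations mark it coding;}
#'   \item{exon / intron}{exact-coordinate feature identity — a predicted
#'     feature counts only if both boundaries coincide with a reference
#'     feature; features are deduplicated across isoforms;}
#'   \item{transcript}{exact CDS-chain identity (every segment boundary).}
#' }
#' At every level `TP + FN` equals the reference feature count and
#' `TP + FP` the prediction feature count.
#'
#' @param predictions,references [as_annotation()] tibbles.
#' @param level One of `"nucleotide"`, `"exon"`, `"intron"`,
#'   `"transcript"`.
#' @return A one-row tibble: `level`, `TP`, `FP`, `FN`.
#' @export
confusion_counts <- function(predictions, references,
                             level = c("nucleotide", "exon", "intron",
                                       "transcript")) {
  level <- match.arg(level)
  counts <- switch(
    level,
    nucleotide = {
      pg <- reduced_footprint(predictions)
      rg <- reduced_footprint(references)
      tp <- sum(IRanges::width(GenomicRanges::intersect(pg, rg)))
      c(TP = tp,
        FP = sum(IRanges::width(pg)) - tp,
        FN = sum(IRanges::width(rg)) - tp)
    },
    exon = exact_set_counts(distinct_features(predictions),
                            distinct_features(references)),
    intron = exact_set_counts(distinct_features(derive_introns(predictions)),
                              distinct_features(derive_introns(references))),
    transcript = exact_set_counts(chain_keys(predictions),
                                  chain_keys(references))
  )
  tibble::tibble(level = level, TP = as.integer(counts["TP"]),
                 FP = as.integer(counts["FP"]), FN = as.integer(counts["FN"]))
}

reduced_footprint <- function(ann) {
  if (nrow(ann) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = ann$contig,
    ranges = IRanges::IRanges(ann$start, ann$end),
    strand = ann$strand
  ))
}

distinct_features <- function(tbl) {
  if (nrow(tbl) == 0) return(character(0))
  unique(paste(tbl$contig, tbl$strand, tbl$start, tbl$end, sep = "|"))
}

chain_keys <- function(ann) {
  if (nrow(ann) == 0) return(character(0))
  keys <- ann |>
    dplyr::arrange(.data$transcript_id, .data$start) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      key = paste(.data$contig[1], .data$strand[1],
                  paste(.data$start, .data$end, sep = "-", collapse = ","),
                  sep = "|"),
      .groups = "drop")
  unique(keys$key)
}

exact_set_counts <- function(pred_keys, ref_keys) {
  tp <- length(intersect(pred_keys, ref_keys))
  c(TP = tp, FP = length(pred_keys) - tp, FN = length(ref_keys) - tp)
}

#' Sensitivity, precision and F1 from confusion counts
#'
#' `Sn = TP / (TP + FN)`, `Pr = TP / (TP + FP)`,
#' `F1 = 2 Sn Pr / (Sn + Pr)`. Any 0/0 is 0 by convention, so `F1 = 0`
#' exactly when `TP = 0`.
#'
#' @param counts A data frame with `TP`, `FP`, `FN` columns (e.g. from
#'   [confusion_counts()]), or a single count when `fp`/`fn` are given.
#' @param fp,fn False positive / false negative counts when `counts` is
#'   the scalar TP.
#' @return The input tibble with `Sn`, `Pr`, `F1` columns appended (or a
#'   one-row tibble for scalar input).
#' @examples
#' sn_pr_f1(8, fp = 4, fn = 2)  # Sn 0.8, Pr 0.667, F1 0.727
#' @export
sn_pr_f1 <- function(counts, fp = NULL, fn = NULL) {
  if (!is.data.frame(counts)) {
    counts <- tibble::tibble(TP = counts, FP = fp, FN = fn)
  }
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  out <- tibble::as_tibble(counts)
  out$Sn <- safe_div(out$TP, out$TP + out$FN)
  out$Pr <- safe_div(out$TP, out$TP + out$FP)
  out$F1 <- safe_div(2 * out$Sn * out$Pr, out$Sn + out$Pr)
  out
}

#' Accuracy statistics at several stringencies
#'
#' Convenience wrapper mapping [confusion_counts()] and [sn_pr_f1()] over
#' stringency levels.
#'
#' @inheritParams confusion_counts
#' @param levels Stringencies to evaluate.
#' @return A tibble with one row per level: counts plus `Sn`, `Pr`, `F1`.
#' @export
accuracy_stats <- function(predictions, references,
                           levels = c("nucleotide", "exon", "intron",
                                      "transcript")) {
  purrr::map_dfr(levels, function(lv) {
    sn_pr_f1(confusion_counts(predictions, references, lv))
  })
}

#' Variance-weighted two-sample ECDF distance (DTS statistic)
#'
#' For pooled sorted values `x_(1) <= ... <= x_(n+m)` with group ECDFs
#' `F` and `G` and pooled ECDF `H`, the statistic is
#' `sum_k |F(x_(k)) - G(x_(k))| * (x_(k+1) - x_(k)) / sqrt(H(x_(k)) (1 - H(x_(k))))`,
#' a Wasserstein-like distance that up-weights discrepancies in the
#' distribution tails. Terms where `H` is 0 or 1, or where consecutive
#' values tie, contribute nothing. The statistic is symmetric in its
#' arguments, zero exactly when the two multisets coincide, and scales
#' linearly with a joint positive rescaling of both samples.
#'
#' @param sample_a,sample_b Non-empty numeric vectors (here typically
#'   per-gene F1 scores).
#' @return A non-negative scalar.
#' @export
dts_statistic <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("dts_statistic: samples must be non-empty", call. = FALSE)
  }
  pooled <- c(sample_a, sample_b)
  o <- order(pooled)
  lab <- c(rep(1L, length(sample_a)), rep(0L, length(sample_b)))[o]
  dts_from_sorted(pooled[o], lab, length(sample_a), length(sample_b))
}

# core computation on the pooled sorted values; `lab` flags membership of
# sample A at each sorted position
dts_from_sorted <- function(x, lab, n, m) {
  N <- n + m
  k <- seq_len(N - 1L)
  ca <- cumsum(lab)[k]
  fa <- ca / n
  fb <- (k - ca) / m
  h <- k / N
  dx <- x[-1L] - x[k]
  wgt <- ifelse(h <= 0 | h >= 1 | dx == 0, 0, dx / sqrt(h * (1 - h)))
  sum(abs(fa - fb) * wgt)
}

#' Permutation test on the DTS statistic
#'
#' Compares two samples' ECDFs with the variance-weighted distance of
#' [dts_statistic()], assessing significance by randomly re-partitioning
#' the pooled values into groups of the original sizes. The p-value uses
#' the add-one estimator
#' `p = (1 + #(permuted >= observed)) / (n_permutations + 1)`, so the
#' smallest attainable p is `1 / (n_permutations + 1)`.
#'
#' @inheritParams dts_statistic
#' @param n_permutations Number of random permutations (default 2000).
#' @param seed Integer seed; required so that results are reproducible.
#' @return An object of class `dts_test` (also `htest`-like): `statistic`,
#'   `p.value`, `n_permutations`, sample sizes. Supports [generics::tidy()]
#'   and [generics::glance()].
#' @export
dts_test <- function(sample_a, sample_b, n_permutations = 2000, seed) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("dts_test: each sample needs at least 2 values", call. = FALSE)
  }
  if (n_permutations < 1) {
    stop("dts_test: n_permutations must be >= 1", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) {
    stop("dts_test: a seed is required for reproducibility", call. = FALSE)
  }
  n <- length(sample_a); m <- length(sample_b); N <- n + m
  pooled <- c(sample_a, sample_b)
  o <- order(pooled)
  x <- pooled[o]
  lab <- c(rep(1L, n), rep(0L, m))[o]
  observed <- dts_from_sorted(x, lab, n, m)
  exceed <- local_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      perm_lab <- integer(N)
      perm_lab[sample.int(N, n)] <- 1L
      dts_from_sorted(x, perm_lab, n, m) >= observed
    }, logical(1))
  })
  p <- (1 + sum(exceed)) / (n_permutations + 1)
  structure(list(statistic = observed, p.value = p,
                 n_permutations = n_permutations, seed = seed,
                 n_a = n, n_b = m,
                 method = "two-sample ECDF permutation test (DTS statistic)"),
            class = "dts_test")
}

# evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.dts_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("DTS = %.6g, p = %.6g (%d permutations, n = %d vs %d)\n",
              x$statistic, x$p.value, x$n_permutations, x$n_a, x$n_b))
  invisible(x)
}

#' @rdname dts_test
#' @param x A `dts_test` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dts_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 n_permutations = x$n_permutations,
                 n_a = x$n_a, n_b = x$n_b, method = x$method)
}

#' @rdname dts_test
#' @exportS3Method generics::glance
glance.dts_test <- function(x, ...) tidy.dts_test(x)

#' Two-proportion z-test (pooled variance, no continuity correction)
#'
#' With pooled proportion `p = (s1 + s2) / (n1 + n2)`,
#' `z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2))` and the two-sided
#' p-value comes from the standard normal. When the pooled proportion is
#' degenerate (0 or 1) the variance vanishes; the test is then defined as
#' `z = 0`, `p = 1`.
#'
#' @param successes_1,n_1,successes_2,n_2 Success counts and trial totals
#'   of the two groups.
#' @return An object of class `prop_ztest` with `statistic` (z),
#'   `p.value`, and the two `estimate`s. Supports [generics::tidy()].
#' @examples
#' two_proportion_ztest(8, 100, 30, 200)  # z = -1.718, p = 0.0857
#' @export
two_proportion_ztest <- function(successes_1, n_1, successes_2, n_2) {
  stopifnot(n_1 >= 1, n_2 >= 1,
            successes_1 >= 0, successes_1 <= n_1,
            successes_2 >= 0, successes_2 <= n_2)
  p1 <- successes_1 / n_1
  p2 <- successes_2 / n_2
  pool <- (successes_1 + successes_2) / (n_1 + n_2)
  if (pool <= 0 || pool >= 1) {
    z <- 0
    p <- 1
  } else {
    z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n_1 + 1 / n_2))
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = z, p.value = p,
                 estimate = c(proportion_1 = p1, proportion_2 = p2),
                 method = "two-proportion z-test (pooled, uncorrected)"),
            class = "prop_ztest")
}

#' @export
print.prop_ztest <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("p1 = %.4g, p2 = %.4g, z = %.4g, p = %.4g\n",
              x$estimate[1], x$estimate[2], x$statistic, x$p.value))
  invisible(x)
}

#' @rdname two_proportion_ztest
#' @param x A `prop_ztest` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.prop_ztest <- function(x, ...) {
  tibble::tibble(estimate1 = unname(x$estimate[1]),
                 estimate2 = unname(x$estimate[2]),
                 statistic = x$statistic, p.value = x$p.value,
                 method = x$method)
}

#' @rdname two_proportion_ztest
#' @exportS3Method generics::glance
glance.prop_ztest <- function(x, ...) tidy.prop_ztest(x)
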