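test_that("identical single-transcript genes pair completely", {
  ref <- mk_ann(list(R = "100-200,300-400"))
  pred <- mk_ann(list(P = "100-200,300-400"))
  asg <- match_transcripts(pred, ref)
  expect_equal(nrow(asg$pairs), 1)
  expect_equal(asg$total_overlap, 202)  # coding length
  expect_length(asg$missing_refs, 0)
  expect_length(asg$false_positive_preds, 0)
})

test_that("transcript assignment is optimal, not greedy", {
  # footprint overlaps: P1xR1 = 100, P1xR2 = 90, P2xR1 = 95, P2xR2 = 0;
  # greedy by largest weight gives 100, the optimum 185 pairs P1-R2, P2-R1
  ref <- mk_ann(list(G = list(
    R1 = "1000-1099",
    R2 = "1200-1289"
  )))
  pred <- mk_ann(list(H = list(
    P1 = "1000-1099,1200-1289",
    P2 = "1005-1099"
  )))
  asg <- match_transcripts(pred, ref)
  expect_equal(asg$total_overlap, 185)
  pairs <- asg$pairs[order(asg$pairs$prediction_id), ]
  expect_equal(pairs$reference_id, c("R2", "R1"))
})

test_that("surplus prediction transcripts are false positives", {
  ref <- mk_ann(list(G = list(R1 = "100-400")))
  pred <- mk_ann(list(H = list(P1 = "100-400", P2 = "150-400")))
  asg <- match_transcripts(pred, ref)
  expect_equal(nrow(asg$pairs), 1)
  expect_equal(asg$false_positive_preds,
               setdiff(c("P1", "P2"), asg$pairs$prediction_id))
})

test_that("assignment equals the exhaustive optimum on random groups", {
  withr::local_seed(99)
  for (trial in 1:60) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    k <- sample(1:(n * m), 1)
    cells <- sample(n * m, k)
    w <- data.frame(row = paste0("r", (cells - 1) %/% m + 1),
                    col = paste0("p", (cells - 1) %% m + 1),
                    weight = sample(0:50, k, replace = TRUE))
    asg <- max_weight_assignment(w, row_order = paste0("r", 1:n),
                                 col_order = paste0("p", 1:m))
    expect_equal(attr(asg, "total_weight"), brute_force_assignment_value(w))
    expect_equal(sum(asg$weight), attr(asg, "total_weight"))
    expect_equal(anyDuplicated(asg$row), 0L)
    expect_equal(anyDuplicated(asg$col), 0L)
  }
})

test_that("identical structures tally fully matched features", {
  ref <- mk_ann(list(R = "100-200,300-400,500-600"))
  pred <- mk_ann(list(P = "100-200,300-400,500-600"))
  asg <- match_transcripts(pred, ref)
  ft <- tally_subfeatures(asg, pred, ref)
  ex <- ft$tally[ft$tally$level == "exon", ]
  expect_equal(c(ex$matched, ex$missing, ex$false_positive, ex$exact),
               c(3L, 0L, 0L, 3L))
  ins <- ft$tally[ft$tally$level == "intron", ]
  expect_equal(c(ins$matched, ins$missing, ins$false_positive, ins$exact),
               c(2L, 0L, 0L, 2L))
})

test_that("a lost terminal exon is counted missing with its position class", {
  ref <- mk_ann(list(R = "100-200,300-400,500-600"))
  pred <- mk_ann(list(P = "100-200,300-400"))
  asg <- match_transcripts(pred, ref)
  ft <- tally_subfeatures(asg, pred, ref)
  ex <- ft$tally[ft$tally$level == "exon", ]
  expect_equal(c(ex$matched, ex$missing, ex$false_positive), c(2L, 1L, 0L))
  expect_equal(
    ft$exon_positions$missing[ft$exon_positions$position_class == "terminal"],
    1L)
  ins <- ft$tally[ft$tally$level == "intron", ]
  expect_equal(c(ins$matched, ins$missing, ins$false_positive), c(1L, 1L, 0L))
})

test_that("an extra exon splitting a reference exon yields FP features", {
  # prediction splits the middle reference exon [300,400] in two
  ref <- mk_ann(list(R = "100-200,300-400,500-600"))
  pred <- mk_ann(list(P = "100-200,300-340,360-400,500-600"))
  asg <- match_transcripts(pred, ref)
  ft <- tally_subfeatures(asg, pred, ref)
  ex <- ft$tally[ft$tally$level == "exon", ]
  expect_gte(ex$false_positive, 1L)
  ins <- ft$tally[ft$tally$level == "intron", ]
  expect_gte(ins$false_positive, 1L)
  # tally identities
  expect_equal(ex$matched + ex$missing, 3L)           # reference exon count
  expect_equal(ex$matched + ex$false_positive, 4L)    # prediction exon count
  expect_equal(ins$matched + ins$missing, 2L)
  expect_equal(ins$matched + ins$false_positive, 3L)
})

test_that("exon matching by max overlap agrees with positional greedy", {
  withr::local_seed(41)
  for (trial in 1:20) {
    ref <- random_annotation(1, seed = 1000 + trial)
    # perturb boundaries slightly to keep collinearity
    p <- tibble::as_tibble(ref)
    p$gene_id <- "P"; p$transcript_id <- "P.t1"
    p$start <- p$start + sample(-5:5, nrow(p), replace = TRUE)
    p$end <- p$end + sample(-5:5, nrow(p), replace = TRUE)
    pred <- as_annotation(p)
    asg <- match_transcripts(pred, ref)
    ft <- tally_subfeatures(asg, pred, ref)
    # greedy-by-position oracle: collinear features match pairwise in order
    n <- nrow(ref)
    ex <- ft$tally[ft$tally$level == "exon", ]
    expect_equal(ex$matched, n)
  }
})

test_that("features of unmatched transcripts count as missing or FP", {
  ref <- mk_ann(list(G = list(R1 = "100-200,300-400", R2 = "100-200")))
  pred <- mk_ann(list(H = list(P1 = "100-200,300-400")))
  asg <- match_transcripts(pred, ref)
  ft <- tally_subfeatures(asg, pred, ref)
  tx <- ft$tally[ft$tally$level == "transcript", ]
  expect_equal(c(tx$matched, tx$missing, tx$false_positive), c(1L, 1L, 0L))
  ex <- ft$tally[ft$tally$level == "exon", ]
  expect_equal(ex$matched + ex$missing, 3L)
})

test_that("both groups empty is an error", {
  empty <- as_annotation(tibble::tibble(
    contig = character(), strand = character(), gene_id = character(),
    transcript_id = character(), start = integer(), end = integer()))
  expect_error(match_transcripts(empty, empty), "empty")
})
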