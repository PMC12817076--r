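test_that("coverage_fraction follows overlap arithmetic", {
  expect_equal(coverage_fraction(data.frame(start = 101, end = 200),
                                 data.frame(start = 151, end = 250)), 0.5)
  expect_equal(coverage_fraction(data.frame(start = 10, end = 20),
                                 data.frame(start = 10, end = 20)), 1.0)
  expect_equal(coverage_fraction(data.frame(start = 1, end = 5),
                                 data.frame(start = 10, end = 20)), 0.0)
  expect_error(coverage_fraction(
    data.frame(contig = "c1", start = 1, end = 5),
    data.frame(contig = "c2", start = 1, end = 5)), "contig")
})

test_that("identical annotations classify as all exact", {
  ref <- mk_ann(list(g1 = "100-200,300-400", g2 = "1000-1500"))
  pred <- mk_ann(list(p1 = "100-200,300-400", p2 = "1000-1500"))
  cl <- classify_genes(pred, ref)
  expect_equal(as.character(cl$outcome), c("exact", "exact"))
})

test_that("a prediction spanning two well-covered references is merged", {
  # oracle: enumerate all pred x ref coverage fractions by hand
  ref <- mk_ann(list(A = "1100-1500", B = "2000-2800"))
  pred <- mk_ann(list(P = "1000-3000"))
  pr <- gene_spans(pred); rf <- gene_spans(ref)
  covs <- coverage_fraction(pr[rep(1, 2), ], rf)
  expect_equal(covs, c(1.0, 1.0))  # both > 0.5: merged by rule
  cl <- classify_genes(pred, ref)
  expect_equal(nrow(cl), 1)
  expect_equal(as.character(cl$outcome), "merged")
  expect_setequal(cl$reference_ids[[1]], c("A", "B"))
  expect_equal(cl$prediction_ids[[1]], "P")
})

test_that("the merged rule needs coverage strictly above the threshold", {
  # B covered exactly 50% (500/1000): not merged; the one-to-one step then
  # pairs P with its larger-overlap reference B (500 vs 401)
  ref <- mk_ann(list(A = "1000-1400", B = "2000-2999"))
  pred <- mk_ann(list(P = "1000-2499"))
  cl <- classify_genes(pred, ref)
  expect_false("merged" %in% as.character(cl$outcome))
  ob <- outcome_by_reference(cl)
  expect_equal(ob$outcome[ob$reference_id == "B"], "inexact")
  expect_equal(ob$outcome[ob$reference_id == "A"], "missing")
  # nudging coverage of B above half flips the call to merged
  pred2 <- mk_ann(list(P = "1000-2500"))
  expect_equal(as.character(classify_genes(pred2, ref)$outcome), "merged")
})

test_that("disjoint predictions inside one reference are fragmented", {
  ref <- mk_ann(list(R = "1000-3000"))
  pred <- mk_ann(list(P1 = "1000-1800", P2 = "2200-3000"))
  cl <- classify_genes(pred, ref)
  expect_equal(as.character(cl$outcome), "fragmented")
  expect_setequal(cl$prediction_ids[[1]], c("P1", "P2"))
})

test_that("overlapping fragments are rejected when fragments must be disjoint", {
  # P1 and P2 overlap on [1700, 1800]; with fragment_mutual_overlap_max = 0
  # the reference is matched inexactly by the larger-overlap prediction and
  # the other prediction stays unassigned
  ref <- mk_ann(list(R = "1000-3000"))
  pred <- mk_ann(list(P1 = "1000-1800", P2 = "1700-3000"))
  cl <- classify_genes(pred, ref)
  ob <- outcome_by_reference(cl)
  expect_equal(ob$outcome, "inexact")
  expect_equal(ob$prediction_ids[[1]], "P2")  # overlap 1301 beats 801
  expect_true("unassigned_prediction" %in% as.character(cl$outcome))
  # relaxing the mutual-overlap cap recovers the fragmented call
  cl2 <- classify_genes(pred, ref,
                        classifier_thresholds(fragment_mutual_overlap_max = 0.2))
  expect_equal(sum(cl2$outcome == "fragmented"), 1)
})

test_that("references with no overlapping prediction are missing", {
  ref <- mk_ann(list(R1 = "1000-2000", R2 = "5000-6000"))
  pred <- mk_ann(list(P = "1000-2000"))
  ob <- outcome_by_reference(classify_genes(pred, ref))
  expect_equal(ob$outcome[ob$reference_id == "R2"], "missing")
})

test_that("matching is strand-aware", {
  ref <- mk_ann(list(R = "1000-2000"))
  pred <- mk_ann(list(P = "1000-2000"), strand = "-")
  cl <- classify_genes(pred, ref)
  ob <- outcome_by_reference(cl)
  expect_equal(ob$outcome, "missing")
  expect_true("unassigned_prediction" %in% as.character(cl$outcome))
})

test_that("one-to-one resolution uses an optimal, not greedy, assignment", {
  # overlaps: P1xR1 = 1000, P1xR2 = 900, P2xR1 = 951, P2xR2 = 0; no span
  # coverage exceeds 50%, so neither merged nor fragmented fires. Greedy
  # would pair P1-R1 (total 1000); the optimum is P1-R2 + P2-R1 (1851).
  ref <- mk_ann(list(R1 = "1000-3000", R2 = "4000-6000"))
  pred <- mk_ann(list(P1 = "2001-4899", P2 = "2050-3000"))
  ob <- outcome_by_reference(classify_genes(pred, ref))
  expect_equal(ob$prediction_ids[[match("R1", ob$reference_id)]], "P2")
  expect_equal(ob$prediction_ids[[match("R2", ob$reference_id)]], "P1")
})

test_that("classification partitions the reference set", {
  ref <- generate_reference(genome_params(n_genes = 60, seed = 5))
  inj <- inject_defects(ref, perturbation_spec(
    n_inexact = 10, n_missing = 6, n_merged = 5, n_fragmented = 5), seed = 6)
  cl <- classify_genes(inj$predictions, ref)
  ob <- outcome_by_reference(cl)
  expect_equal(sort(ob$reference_id), sort(unique(ref$gene_id)))
  expect_equal(anyDuplicated(ob$reference_id), 0L)
})

test_that("raising thresholds is monotone in the defect counts", {
  ref <- generate_reference(genome_params(n_genes = 80, seed = 7))
  inj <- inject_defects(ref, perturbation_spec(
    n_inexact = 15, n_merged = 8, n_fragmented = 8), seed = 8)
  merged_counts <- vapply(c(0.3, 0.5, 0.7), function(th) {
    cl <- classify_genes(inj$predictions, ref,
                         classifier_thresholds(merged_ref_coverage = th))
    sum(cl$outcome == "merged")
  }, numeric(1))
  expect_true(all(diff(merged_counts) <= 0))
  frag_counts <- vapply(c(0.3, 0.5, 0.7), function(th) {
    cl <- classify_genes(inj$predictions, ref,
                         classifier_thresholds(fragment_pred_coverage = th))
    sum(cl$outcome == "fragmented")
  }, numeric(1))
  expect_true(all(diff(frag_counts) <= 0))
})

test_that("thresholds outside the unit interval are rejected", {
  expect_error(classifier_thresholds(merged_ref_coverage = 1.2), "\\[0, 1\\]")
  expect_error(classifier_thresholds(fragment_pred_coverage = -0.1),
               "\\[0, 1\\]")
})
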