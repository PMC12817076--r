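test_that("a zero-perturbation pair reports a perfect annotation", {
  ref <- generate_reference(genome_params(n_genes = 25, seed = 51))
  inj <- inject_defects(ref, perturbation_spec(), seed = 52)
  rep <- evaluate_report(inj$predictions, ref)
  expect_equal(rep$gene_outcomes$n[rep$gene_outcomes$outcome == "exact"], 25L)
  expect_true(all(rep$accuracy$F1 == 1))
  expect_true(all(rep$per_gene_f1$F1 == 1))
  expect_true(all(rep$tally$missing == 0))
  expect_true(all(rep$tally$false_positive == 0))
})

test_that("one injected merge consumes two reference genes", {
  ref <- generate_reference(genome_params(n_genes = 30, seed = 53))
  inj <- inject_defects(ref, perturbation_spec(n_merged = 1), seed = 54)
  rep <- evaluate_report(inj$predictions, ref)
  expect_equal(rep$gene_outcomes$n[rep$gene_outcomes$outcome == "merged"], 2L)
  expect_equal(sum(rep$classification$outcome == "merged"), 1L)
})

test_that("feature tallies satisfy their conservation identities", {
  ref <- generate_reference(genome_params(n_genes = 60,
                                          isoform_probability = 0.4,
                                          seed = 55))
  inj <- inject_defects(ref, perturbation_spec(
    n_inexact = 12, n_missing = 6, n_merged = 6, n_fragmented = 6,
    spurious_transcript_rate = 0.15), seed = 56)
  rep <- evaluate_report(inj$predictions, ref)
  n_ref_tx <- length(unique(ref$transcript_id))
  n_pred_tx <- length(unique(inj$predictions$transcript_id))
  tx <- rep$tally[rep$tally$level == "transcript", ]
  expect_equal(tx$matched + tx$missing, n_ref_tx)
  expect_equal(tx$matched + tx$false_positive, n_pred_tx)
  ex <- rep$tally[rep$tally$level == "exon", ]
  expect_equal(ex$matched + ex$missing, nrow(ref))
  expect_equal(ex$matched + ex$false_positive, nrow(inj$predictions))
  ins <- rep$tally[rep$tally$level == "intron", ]
  expect_equal(ins$matched + ins$missing, nrow(derive_introns(ref)))
  expect_equal(ins$matched + ins$false_positive,
               nrow(derive_introns(inj$predictions)))
  # exon position breakdown is consistent with the exon totals
  expect_equal(sum(rep$exon_positions$matched), ex$matched)
  expect_equal(sum(rep$exon_positions$missing), ex$missing)
  expect_equal(sum(rep$exon_positions$false_positive), ex$false_positive)
})

test_that("gold-standard restriction equals pre-filtering the reference", {
  ref <- generate_reference(genome_params(n_genes = 40, seed = 57))
  inj <- inject_defects(ref, perturbation_spec(
    n_inexact = 8, n_missing = 4, n_merged = 4, n_fragmented = 4),
    seed = 58)
  ids <- gene_spans(ref)$gene_id
  subset_ids <- ids[seq(1, length(ids), by = 2)]
  rep_restricted <- evaluate_report(inj$predictions, ref,
                                    gold_standard = subset_ids)
  pre <- as_annotation(
    tibble::as_tibble(ref)[ref$gene_id %in% subset_ids, ],
    source_label = "prefiltered")
  rep_pre <- evaluate_report(inj$predictions, pre)
  expect_equal(rep_restricted$gene_outcomes, rep_pre$gene_outcomes)
  expect_equal(rep_restricted$tally, rep_pre$tally)
  expect_equal(rep_restricted$accuracy, rep_pre$accuracy)
  expect_equal(sum(rep_restricted$gene_outcomes$n), length(subset_ids))
  expect_error(evaluate_report(inj$predictions, ref,
                               gold_standard = "not_a_gene"),
               "no reference gene")
})

test_that("per-gene F1 is 1 for exact genes and 0 for missing genes", {
  ref <- generate_reference(genome_params(n_genes = 30, seed = 59))
  inj <- inject_defects(ref, perturbation_spec(n_missing = 6, n_inexact = 6),
                        seed = 60)
  rep <- evaluate_report(inj$predictions, ref)
  f1 <- rep$per_gene_f1
  expect_true(all(f1$F1[f1$outcome == "exact"] == 1))
  expect_true(all(f1$F1[f1$outcome == "missing"] == 0))
  expect_true(all(f1$F1[f1$outcome == "inexact"] > 0 &
                    f1$F1[f1$outcome == "inexact"] < 1))
})

test_that("agreement partition cells are disjoint and sum to the total", {
  ref <- generate_reference(genome_params(n_genes = 50, seed = 61))
  mk_pipeline <- function(seed, n_missing) {
    inject_defects(ref, perturbation_spec(n_inexact = 10,
                                          n_missing = n_missing),
                   seed = seed)$predictions
  }
  sets <- list(alpha = mk_pipeline(62, 5), beta = mk_pipeline(63, 8),
               gamma = mk_pipeline(64, 0))
  part <- agreement_partition(sets, ref)
  match_cells <- part$cells[part$cells$category == "match", ]
  expect_equal(sum(match_cells$n) + part$n_unmatched, 50)
  expect_equal(match_cells$per_1000, 1000 * match_cells$n / 50)
  # gamma misses nothing, so every gene is matched by at least gamma
  expect_equal(part$n_unmatched, 0)
})

test_that("identical prediction sets all land in the full subset cell", {
  ref <- generate_reference(genome_params(n_genes = 30, seed = 65))
  pred <- inject_defects(ref, perturbation_spec(), seed = 66)$predictions
  part <- agreement_partition(list(a = pred, b = pred, c = pred), ref)
  match_cells <- part$cells[part$cells$category == "match", ]
  expect_equal(nrow(match_cells), 1)
  expect_equal(match_cells$pipelines, "a+b+c")
  expect_equal(match_cells$per_1000, 1000)
})

test_that("a gene missed by one pipeline lands in the K-1 subset cell", {
  ref <- generate_reference(genome_params(n_genes = 30, seed = 67))
  full <- inject_defects(ref, perturbation_spec(), seed = 68)$predictions
  drop_one <- as_annotation(
    tibble::as_tibble(full)[full$gene_id != paste0("p_", "g00004"), ],
    source_label = "dropper")
  part <- agreement_partition(list(a = full, b = drop_one, c = full), ref)
  mc <- part$cells[part$cells$category == "match", ]
  expect_equal(mc$n[mc$pipelines == "a+c"], 1)
  expect_equal(mc$n[mc$pipelines == "a+b+c"], 29)
  miss <- part$cells[part$cells$category == "missing", ]
  expect_equal(miss$pipelines, "b")
  expect_equal(miss$n, 1)
})

test_that("reports write auditable TSV and JSON artifacts", {
  ref <- generate_reference(genome_params(n_genes = 15, seed = 69))
  inj <- inject_defects(ref, perturbation_spec(n_inexact = 3), seed = 70)
  rep <- evaluate_report(inj$predictions, ref)
  dir <- withr::local_tempdir()
  paths <- write_report(rep, dir)
  expect_true(all(file.exists(paths)))
  cls <- readLines(file.path(dir, "gene_classification.tsv"))
  expect_match(cls[1], "^# annoclass")
  expect_match(cls[2], "^outcome\t")
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$total_reference_genes, 15)
})

test_that("glance on a report yields a one-row tidy summary", {
  ref <- generate_reference(genome_params(n_genes = 12, seed = 71))
  inj <- inject_defects(ref, perturbation_spec(n_missing = 2), seed = 72)
  g <- glance(evaluate_report(inj$predictions, ref))
  expect_equal(nrow(g), 1)
  expect_equal(g$n_missing, 2L)
  expect_equal(g$total_reference_genes, 12)
})

test_that("the shipped synthetic example fixtures evaluate cleanly", {
  ref <- read_gff3(system.file("extdata", "synthetic_reference.gff3",
                               package = "annoclass"))
  pred <- read_gff3(system.file("extdata", "synthetic_predictions.gff3",
                                package = "annoclass"))
  truth <- utils::read.delim(system.file(
    "extdata", "synthetic_truth_labels.tsv", package = "annoclass"))
  rep <- evaluate_report(pred, ref)
  got <- outcome_by_reference(rep$classification)
  expect_identical(got$outcome[match(truth$gene_id, got$reference_id)],
                   truth$outcome)
  recs <- read_busco_table(system.file(
    "extdata", "synthetic_busco_full_table.tsv", package = "annoclass"))
  curated <- read_id_list(system.file(
    "extdata", "synthetic_curated_ids.txt", package = "annoclass"))
  gold <- build_gold_standard(recs, curated)
  expect_gte(nrow(gold), length(curated))
})
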