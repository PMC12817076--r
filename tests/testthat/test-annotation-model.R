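test_that("a minimal gene/mRNA/CDS hierarchy parses into one gene", {
  txt <- paste(
    "##gff-version 3",
    "c1\tsrc\tgene\t1\t500\t.\t+\t.\tID=g1",
    "c1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=t1;Parent=g1",
    "c1\tsrc\tCDS\t1\t500\t.\t+\t0\tParent=t1",
    sep = "\n")
  ann <- read_gff3(txt)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$gene_id, "g1")
  expect_equal(ann$start, 1L)
  expect_equal(ann$end, 500L)
  expect_equal(cds_position_class(ann)$position_class, "single")
})

test_that("a multi-parent CDS row is attached to every listed transcript", {
  txt <- paste(
    "c1\tsrc\tgene\t1\t900\t.\t+\t.\tID=g1",
    "c1\tsrc\tmRNA\t1\t900\t.\t+\t.\tID=t1;Parent=g1",
    "c1\tsrc\tmRNA\t1\t900\t.\t+\t.\tID=t2;Parent=g1",
    "c1\tsrc\tCDS\t1\t300\t.\t+\t0\tParent=t1,t2",
    "c1\tsrc\tCDS\t500\t900\t.\t+\t0\tParent=t1",
    sep = "\n")
  ann <- read_gff3(txt)
  expect_setequal(unique(ann$transcript_id), c("t1", "t2"))
  expect_equal(sum(ann$transcript_id == "t2"), 1)
  expect_equal(sum(ann$transcript_id == "t1"), 2)
})

test_that("malformed GFF3 rows raise located errors", {
  gene <- "c1\tsrc\tgene\t1\t500\t.\t+\t.\tID=g1"
  mrna <- "c1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=t1;Parent=g1"
  # end < start, naming the line
  expect_error(
    read_gff3(paste(gene, mrna, "c1\tsrc\tCDS\t200\t100\t.\t+\t0\tParent=t1",
                    sep = "\n")),
    "line 3.*coordinates")
  # wrong column count
  expect_error(read_gff3("c1\tsrc\tgene\t1\t500"), "9 tab-separated")
  # unknown transcript parent
  expect_error(
    read_gff3(paste(gene, mrna, "c1\tsrc\tCDS\t1\t99\t.\t+\t0\tParent=tX",
                    sep = "\n")),
    "unknown transcript parent 'tX'")
  # unknown gene parent
  expect_error(
    read_gff3("c1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=t1;Parent=gX"),
    "unknown gene parent 'gX'")
  # duplicate gene id
  expect_error(
    read_gff3(paste(gene, gene, sep = "\n")),
    "duplicate gene ID 'g1'")
})

test_that("unstranded features error strictly and skip leniently", {
  txt <- paste(
    "c1\tsrc\tgene\t1\t500\t.\t.\t.\tID=g1",
    "c1\tsrc\tmRNA\t1\t500\t.\t.\t.\tID=t1;Parent=g1",
    "c1\tsrc\tCDS\t1\t500\t.\t.\t0\tParent=t1",
    sep = "\n")
  expect_error(read_gff3(txt), "strand")
  expect_warning(ann <- read_gff3(txt, lenient = TRUE), "skipped")
  expect_equal(nrow(ann), 0)
})

test_that("write/parse round trip is the identity on structure", {
  ann <- mk_ann(list(
    g1 = "100-200,300-400,500-650",
    g2 = list(g2.t1 = "1000-1100,1300-1500", g2.t2 = "1000-1100")
  ))
  rt <- read_gff3(paste(write_gff3(ann), collapse = "\n"))
  expect_ann_equal(ann, rt)
  # generated fixtures round-trip too
  for (seed in c(11, 12, 13)) {
    r <- random_annotation(20, seed)
    expect_ann_equal(r, read_gff3(paste(write_gff3(r), collapse = "\n")))
  }
})

test_that("an empty annotation writes a header-only file", {
  empty <- as_annotation(tibble::tibble(
    contig = character(), strand = character(), gene_id = character(),
    transcript_id = character(), start = integer(), end = integer()))
  expect_equal(write_gff3(empty), "##gff-version 3")
})

test_that("GFF3 output is grouped by contig and sorted by gene start", {
  a <- mk_ann(list(g2 = "500-600", g1 = "100-200"))
  b <- mk_ann(list(h1 = "50-80"), contig = "c0")
  both <- as_annotation(dplyr::bind_rows(as.data.frame(a), as.data.frame(b)))
  lines <- write_gff3(both)
  gene_lines <- grep("\tgene\t", lines, value = TRUE)
  expect_equal(gff_field(gene_lines, 1), c("c0", "c1", "c1"))
  expect_equal(as.integer(gff_field(gene_lines, 4)), c(50L, 100L, 500L))
})

test_that("introns are inter-CDS gaps with the adjacency convention", {
  expect_equal(derive_introns(mk_ann(list(g = "100-200,300-400")))$start, 201L)
  expect_equal(derive_introns(mk_ann(list(g = "100-200,300-400")))$end, 299L)
  expect_equal(nrow(derive_introns(mk_ann(list(g = "100-200")))), 0)
  # zero-length gap: adjacent segments produce no intron
  expect_equal(nrow(derive_introns(mk_ann(list(g = "100-200,201-300")))), 0)
})

test_that("overlapping CDS segments within a transcript are rejected", {
  expect_error(mk_ann(list(g = "100-200,150-300")), "overlapping")
})

test_that("coding length plus intron lengths equals the transcript span", {
  for (seed in 21:25) {
    ann <- random_annotation(15, seed)
    ts <- transcript_spans(ann)
    ins <- derive_introns(ann)
    intron_len <- vapply(ts$transcript_id, function(tx) {
      sel <- ins$transcript_id == tx
      sum(ins$end[sel] - ins$start[sel] + 1L)
    }, numeric(1))
    expect_equal(ts$coding_length + unname(intron_len),
                 ts$end - ts$start + 1L)
  }
})

test_that("position classes follow transcription direction", {
  plus <- cds_position_class(mk_ann(list(g = "1-10,20-30,40-50")))
  expect_equal(plus$position_class[order(plus$start)],
               c("initial", "internal", "terminal"))
  minus <- cds_position_class(mk_ann(list(g = "1-10,20-30,40-50"),
                                     strand = "-"))
  expect_equal(minus$position_class[order(minus$start)],
               c("terminal", "internal", "initial"))
})

test_that("gene ids reused across contigs are rejected", {
  expect_error(as_annotation(data.frame(
    contig = c("c1", "c2"), strand = "+", gene_id = "g1",
    transcript_id = c("t1", "t2"), start = 1L, end = 10L)),
    "reused")
})

test_that("id lists skip comments and blanks", {
  ids <- read_id_list("# curated\n\ngeneA\n geneB \ngeneA")
  expect_equal(ids, c("geneA", "geneB"))
})
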