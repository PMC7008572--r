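test_that("BED12 exon blocks sum to the transcript length", {
  path <- write_tmp(bed12_line("chr1", 1000, sizes = c(100L, 200L),
                               gaps = 500L, name = "NM_10"))
  tx <- load_transcripts(path)
  expect_equal(nrow(tx), 1L)
  expect_equal(tx$length_L, 300L)
  expect_equal(tx$exon_starts[[1]], c(1000L, 1600L))
  expect_equal(tx$exon_ends[[1]], c(1100L, 1800L))
})

test_that("longest isoform per gene is kept, ties broken by smallest id", {
  lines <- c(
    bed12_line("chr1", 0, sizes = 500L, name = "NM_a"),
    bed12_line("chr1", 0, sizes = 800L, name = "NM_b"),
    bed12_line("chr2", 0, sizes = 800L, name = "NM_2"),
    bed12_line("chr2", 0, sizes = 800L, name = "NM_1"))
  gm <- data.frame(transcript_id = c("NM_a", "NM_b", "NM_2", "NM_1"),
                   gene_id = c("G1", "G1", "G2", "G2"))
  tx <- load_transcripts(write_tmp(lines), gene_map = gm)
  expect_setequal(tx$transcript_id, c("NM_b", "NM_1"))
  expect_equal(tx[tx$gene_id == "G1", ]$length_L, 800L)
  expect_equal(tx[tx$gene_id == "G2", ]$transcript_id, "NM_1")
})

test_that("loading is idempotent and order-invariant", {
  lines <- c(
    bed12_line("chr1", 0, sizes = 500L, name = "t1"),
    bed12_line("chr1", 900, sizes = c(50L, 60L), gaps = 10L, name = "t2"),
    bed12_line("chr2", 0, sizes = 300L, name = "t3", strand = "-"))
  p1 <- write_tmp(lines)
  p2 <- write_tmp(rev(lines))
  a <- load_transcripts(p1); b <- load_transcripts(p1); c <- load_transcripts(p2)
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_equal(as.data.frame(a), as.data.frame(c))
})

test_that("malformed records error with the line number; zero-length exons are rejected with a log", {
  bad <- c(bed12_line("chr1", 0, sizes = 100L), "chr1\tnotanumber\t10\tx")
  expect_error(load_transcripts(write_tmp(bad)), "line 2")
  short <- c("chr1\t0\t100\tonlyfour")
  expect_error(load_transcripts(write_tmp(short), format = "bed12"),
               "line 1")
  zl <- c(bed12_line("chr1", 0, sizes = 100L, name = "ok"),
          bed12_line("chr1", 500, sizes = c(50L, 0L), gaps = 10L, name = "zz"))
  expect_message(tx <- load_transcripts(write_tmp(zl)), "zero-length")
  expect_equal(tx$transcript_id, "ok")
  expect_equal(attr(tx, "log")$n_rejected_zero_exon, 1L)
})

test_that("genePred dialects (refFlat and extended) load with gene symbols", {
  refflat <- paste("GENEA", "NM_1", "chr1", "+", "100", "400", "100", "400",
                   "2", "100,300,", "200,400,", sep = "\t")
  tx <- load_transcripts(write_tmp(refflat), format = "genepred")
  expect_equal(tx$gene_id, "GENEA")
  expect_equal(tx$length_L, 200L)
  expect_equal(tx$exon_starts[[1]], c(100L, 300L))

  gpext <- paste("NM_9", "chr2", "-", "0", "500", "0", "500", "1",
                 "0,", "500,", "0", "GENEB", sep = "\t")
  tx2 <- load_transcripts(write_tmp(gpext), format = "genepred")
  expect_equal(tx2$gene_id, "GENEB")
  expect_equal(tx2$strand, "-")
  expect_equal(tx2$length_L, 500L)

  # auto-detection distinguishes the dialects
  expect_equal(load_transcripts(write_tmp(refflat))$gene_id, "GENEA")
})

test_that("attach_expression computes count per kilobase and drops orphans with a log", {
  lines <- c(bed12_line("chr1", 0, sizes = 1000L, name = "t1"),
             bed12_line("chr1", 2000, sizes = 500L, name = "t2"),
             bed12_line("chr1", 4000, sizes = 2000L, name = "t3"))
  gm <- data.frame(transcript_id = c("t1", "t2", "t3"),
                   gene_id = c("g1", "g2", "g3"))
  tx <- load_transcripts(write_tmp(lines), gene_map = gm)
  counts <- data.frame(gene_id = c("g1", "g2", "orphan"),
                       s1 = c(300, 0, 7))
  expr <- attach_expression(tx, counts)
  expect_equal(expr[expr$gene_id == "g1", ]$norm_expression, 300)
  expect_equal(expr[expr$gene_id == "g2", ]$norm_expression, 0)
  expect_false("orphan" %in% expr$gene_id)
  rec <- attr(expr, "reconciliation")
  expect_equal(rec$n_counts_without_model, 1L)
  expect_equal(rec$n_models_without_counts, 1L)
})

test_that("duplicate gene rows in the counts table are an error naming them", {
  lines <- bed12_line("chr1", 0, sizes = 1000L, name = "t1")
  tx <- load_transcripts(write_tmp(lines))
  counts <- data.frame(gene_id = c("t1", "t1"), s1 = c(1, 2))
  expect_error(attach_expression(tx, counts), "duplicate.*t1")
})

test_that("featureCounts layout with comment line and annotation columns is read", {
  lines <- c("# Program:featureCounts v1.5.1",
             paste("Geneid", "Chr", "Start", "End", "Strand", "Length",
                   "s1.bam", "s2.bam", sep = "\t"),
             "gA\tchr1\t1\t100\t+\t100\t11\t21",
             "gB\tchr1\t200\t400\t-\t200\t12\t22")
  cnt <- read_feature_counts(write_tmp(lines))
  expect_equal(names(cnt), c("gene_id", "s1.bam", "s2.bam"))
  expect_equal(cnt$s2.bam, c(21, 22))
})
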