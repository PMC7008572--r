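test_that("adjacent equal-depth BedGraph intervals merge into one logical region", {
  track <- read_bedgraph(write_tmp(c("chr1\t0\t10\t5", "chr1\t10\t20\t5")))
  rle <- track[["chr1"]]
  expect_equal(as.numeric(S4Vectors::runValue(rle)), 5)
  expect_equal(as.integer(S4Vectors::runLength(rle)), 20L)
})

test_that("empty and comment-only BedGraph files give an empty track", {
  expect_length(read_bedgraph(write_tmp(character())), 0)
  expect_length(read_bedgraph(write_tmp(c("track type=bedGraph", "# c"))), 0)
})

test_that("invalid BedGraph records are rejected with the line number", {
  expect_error(read_bedgraph(write_tmp("chr1\t10\t10\t5")), "end <= start.*line 1")
  expect_error(read_bedgraph(write_tmp(c("chr1\t0\t5\t1", "chr1\t5\t9\t-2"))),
               "negative depth.*line 2")
  expect_error(read_bedgraph(write_tmp("chr1\t0\tten\t5")), "line 1")
  expect_error(read_bedgraph(write_tmp(c("track x", "chr1\t0\t10\t1",
                                         "chr1\t5\t15\t2"))),
               "overlapping.*chr1.*line 3")
})

test_that("space-delimited BedGraph is accepted", {
  track <- read_bedgraph(write_tmp("chr1 3 7 2"))
  expect_equal(as.numeric(track[["chr1"]]), c(0, 0, 0, 2, 2, 2, 2))
})

test_that("chromosome aliases apply only when requested", {
  lines <- "1\t0\t4\t9"
  t1 <- read_bedgraph(write_tmp(lines))
  expect_named(t1, "1")
  t2 <- read_bedgraph(write_tmp(lines), aliases = c("1" = "chr1"))
  expect_named(t2, "chr1")
})

test_that("projection extracts exonic bases 5' to 3' and excludes introns", {
  # constant depth 5 across the locus; two exons of 100+200
  lines <- "chr1\t0\t2000\t5"
  track <- read_bedgraph(write_tmp(lines))
  tx <- load_transcripts(write_tmp(
    bed12_line("chr1", 100, sizes = c(100L, 200L), gaps = 300L)))
  d <- project_coverage(track, tx)[["tx1"]]
  expect_length(d, 300)
  expect_true(all(d == 5))
  expect_equal(sum(d), 1500)

  # depth only inside the intron -> all zero
  track2 <- read_bedgraph(write_tmp("chr1\t220\t280\t9"))
  d2 <- project_coverage(track2, tx)[["tx1"]]
  expect_true(all(d2 == 0))
})

test_that("minus-strand projection reverses genomic order so k = 0 is the TSS", {
  tx <- load_transcripts(write_tmp(
    bed12_line("chr1", 100, sizes = c(50L, 50L), gaps = 100L, strand = "-")))
  # depth 7 only at the highest-coordinate exonic base (genomic 299)
  track <- read_bedgraph(write_tmp("chr1\t299\t300\t7"))
  d <- project_coverage(track, tx)[["tx1"]]
  expect_equal(d[1], 7)
  expect_true(all(d[-1] == 0))
})

test_that("absent chromosome projects to zeros and is counted, not an error", {
  tx <- load_transcripts(write_tmp(bed12_line("chrZ", 0, sizes = 100L)))
  track <- read_bedgraph(write_tmp("chr1\t0\t10\t1"))
  cov <- project_coverage(track, tx)
  expect_true(all(cov[["tx1"]] == 0))
  expect_equal(attr(cov, "n_missing_chrom"), 1L)
})

test_that("projection agrees with a brute-force per-base oracle on random fixtures", {
  set.seed(11)
  for (i in 1:25) {
    n_iv <- sample(1:8, 1)
    pts <- sort(sample(0:500, 2 * n_iv))             # disjoint by construction
    starts <- pts[seq(1, 2 * n_iv, 2)]
    ends <- pts[seq(2, 2 * n_iv, 2)]
    keep <- ends > starts
    lines <- sprintf("chrR\t%d\t%d\t%d", starts[keep], ends[keep],
                     sample(1:9, sum(keep), replace = TRUE))
    sizes <- sample(5:60, sample(1:3, 1), replace = TRUE)
    gaps <- sample(5:50, length(sizes) - 1, replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    gstart <- sample(0:200, 1)
    tx <- load_transcripts(write_tmp(
      bed12_line("chrR", gstart, sizes = sizes, gaps = gaps, strand = strand)))
    d <- project_coverage(read_bedgraph(write_tmp(lines)), tx)[["tx1"]]
    d_oracle <- project_oracle(lines, tx$exon_starts[[1]], tx$exon_ends[[1]],
                               strand)
    expect_equal(d, d_oracle)
  }
})

test_that("projection is linear and strand flip exactly reverses d", {
  l1 <- c("chrL\t0\t50\t2", "chrL\t80\t120\t3")
  l2 <- c("chrL\t20\t100\t4")
  tx_p <- load_transcripts(write_tmp(
    bed12_line("chrL", 10, sizes = c(30L, 40L), gaps = 20L, strand = "+")))
  tx_m <- load_transcripts(write_tmp(
    bed12_line("chrL", 10, sizes = c(30L, 40L), gaps = 20L, strand = "-")))
  sum_lines <- write_tmp(c("chrL\t0\t20\t2", "chrL\t20\t50\t6", "chrL\t50\t80\t4",
                           "chrL\t80\t100\t7", "chrL\t100\t120\t3"))
  d1 <- project_coverage(read_bedgraph(write_tmp(l1)), tx_p)[["tx1"]]
  d2 <- project_coverage(read_bedgraph(write_tmp(l2)), tx_p)[["tx1"]]
  dsum <- project_coverage(read_bedgraph(sum_lines), tx_p)[["tx1"]]
  expect_equal(d1 + d2, dsum)
  dm <- project_coverage(read_bedgraph(write_tmp(l1)), tx_m)[["tx1"]]
  expect_equal(dm, rev(d1))
})
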