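# compact two-regime mu fixture: tight symmetric spread at high
# expression, bimodal split below the onset rank
two_regime_records <- function(n, onset, seed, split = 0.9, spread = 0.03) {
  set.seed(seed)
  mu <- c(runif(onset, -spread, spread),
          sample(c(-split, split), n - onset, replace = TRUE) +
            runif(n - onset, -0.05, 0.05))
  data.frame(transcript_id = sprintf("t%05d", seq_len(n)),
             mu = mu,
             norm_expression = sort(rexp(n, 1 / 100) + 1, decreasing = TRUE))
}

test_that("no window triggering means every ranked transcript passes, with a warning", {
  set.seed(8)
  recs <- data.frame(transcript_id = sprintf("t%03d", 1:600),
                     mu = 2 * c(rbeta(300, 2, 2), 1 - rbeta(300, 2, 2)) - 1,
                     norm_expression = 600:1)
  ranked <- rank_transcripts(recs)
  scan <- find_cutoff(ranked, clear_config())
  expect_null(scan$cutoff)
  expect_length(scan$pass_ids, 600)
  expect_match(paste(scan$warnings, collapse = " "), "no window exceeded")
})

test_that("fewer ranked transcripts than one window passes everything with a warning", {
  recs <- data.frame(transcript_id = letters[1:5], mu = rep(0, 5),
                     norm_expression = 5:1)
  scan <- find_cutoff(rank_transcripts(recs), clear_config())
  expect_null(scan$cutoff)
  expect_length(scan$pass_ids, 5)
  expect_match(scan$warnings[1], "fewer ranked transcripts")
})

test_that("any exceedance of the threshold triggers, on either parameter", {
  cfg <- clear_config(window_size = 50, window_step = 10, n_bins = 25)
  # all mu collapsed to +0.97: a fits >> 2, so the very first window triggers
  recs <- data.frame(transcript_id = sprintf("t%03d", 1:100),
                     mu = rep(0.97, 100), norm_expression = 100:1)
  scan <- find_cutoff(rank_transcripts(recs), cfg)
  expect_equal(scan$cutoff$window_index, 1L)
  expect_gt(scan$cutoff$a, 2)
  # mirrored toward -1: the b parameter triggers instead
  recs$mu <- rep(-0.97, 100)
  scan_b <- find_cutoff(rank_transcripts(recs), cfg)
  expect_gt(scan_b$cutoff$b, 2)
  # a threshold just above the fitted value must not trigger
  cfg_hi <- clear_config(window_size = 50, window_step = 10,
                         param_threshold = 1e6, param_upper = 1e7)
  expect_null(find_cutoff(rank_transcripts(recs), cfg_hi)$cutoff)
})

test_that("detected cutoff lands within one window span of the planted onset", {
  ranked <- rank_transcripts(two_regime_records(7000, 2000, seed = 101))
  scan <- find_cutoff(ranked, clear_config())
  expect_false(is.null(scan$cutoff))
  expect_gte(scan$cutoff$rank, 1900)
  expect_lte(scan$cutoff$rank, 2150)
  # scan stops at the first trigger
  expect_equal(scan$cutoff$window_index, nrow(scan$windows))
})

test_that("the passing set is strictly above the boundary expression and forms a rank prefix", {
  recs <- two_regime_records(3000, 800, seed = 7)
  # plant expression ties at the eventual boundary region
  recs$norm_expression <- ceiling(recs$norm_expression / 5) * 5
  ranked <- rank_transcripts(recs)
  scan <- find_cutoff(ranked, clear_config())
  expect_false(is.null(scan$cutoff))
  pass_rank <- ranked$rank[ranked$transcript_id %in% scan$pass_ids]
  if (length(pass_rank))
    expect_equal(sort(pass_rank), seq_len(max(pass_rank)))  # prefix, no gaps
  boundary <- scan$cutoff$boundary_expression
  expect_true(all(ranked$norm_expression[ranked$transcript_id %in% scan$pass_ids] > boundary))
  # boundary ties are excluded
  tied <- ranked$transcript_id[ranked$norm_expression == boundary]
  expect_false(any(tied %in% scan$pass_ids))
})

test_that("run_clear is scale-invariant when expression derives from coverage", {
  wex <- make_worked_example()
  tx <- load_transcripts(write_tmp(wex$annotation), gene_map = wex$gene_map)
  t1 <- read_bedgraph(write_tmp(wex$bedgraph))
  # multiply every depth by 10
  f <- do.call(rbind, strsplit(wex$bedgraph, "\t"))
  lines10 <- sprintf("%s\t%s\t%s\t%d", f[, 1], f[, 2], f[, 3],
                     10L * as.integer(f[, 4]))
  t10 <- read_bedgraph(write_tmp(lines10))
  r1 <- suppressWarnings(run_clear(t1, tx, sample_id = "s"))
  r10 <- suppressWarnings(run_clear(t10, tx, sample_id = "s"))
  expect_equal(r1$records$mu, r10$records$mu)
  expect_equal(r1$ranked$transcript_id, r10$ranked$transcript_id)
  expect_equal(r1$expression_source, "coverage_per_base")
})

test_that("per-sample TSV and manifest round-trip the result", {
  wex <- make_worked_example()
  tx <- load_transcripts(write_tmp(wex$annotation), gene_map = wex$gene_map)
  res <- suppressWarnings(run_clear(write_tmp(wex$bedgraph, ".bedgraph"), tx,
                                    counts = write_tmp(wex$counts),
                                    sample_id = "wex1"))
  dir <- file.path(tempfile(), "out")
  paths <- write_clear_result(res, dir)
  expect_true(all(file.exists(paths)))
  back <- read_clear_result(paths[["tsv"]])
  expect_equal(back$sample_id, "wex1")
  expect_setequal(back$records$transcript_id[back$records$pass],
                  res$records$transcript_id[res$records$pass])
  man <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(man$expression_source, "counts_table")
  expect_equal(man$counts$n_undefined, 1L)
  expect_equal(man$counts$n_pass, 5L)
})
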