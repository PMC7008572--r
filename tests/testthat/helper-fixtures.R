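# shared fixtures and independent oracles

# naive per-base loop oracle for mu (kept deliberately dumb)
mu_oracle <- function(d) {
  L <- length(d)
  num <- 0; den <- 0
  for (k in seq_len(L)) {
    num <- num + (k - 1) * d[k]
    den <- den + d[k]
  }
  if (den == 0) return(NA_real_)
  (2 / L) * (num / den) - 1
}

# brute-force projection oracle: materialise the whole chromosome
project_oracle <- function(bedgraph_lines, exon_starts, exon_ends, strand) {
  f <- do.call(rbind, strsplit(bedgraph_lines, "\t"))
  chrom_len <- max(as.integer(f[, 3]), max(exon_ends)) + 10L
  genome <- numeric(chrom_len)
  for (i in seq_len(nrow(f))) {
    s <- as.integer(f[i, 2]); e <- as.integer(f[i, 3])
    genome[(s + 1):e] <- genome[(s + 1):e] + as.numeric(f[i, 4])
  }
  d <- unlist(lapply(seq_along(exon_starts), function(j)
    genome[(exon_starts[j] + 1):exon_ends[j]]))
  if (strand == "-") d <- rev(d)
  d
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# single-gene BED12 line builder
bed12_line <- function(chrom, start, sizes, gaps = integer(0), name = "tx1",
                       strand = "+") {
  starts_rel <- cumsum(c(0L, head(sizes, -1L) + gaps))
  end <- start + starts_rel[length(sizes)] + sizes[length(sizes)]
  sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
          chrom, start, end, name, strand, start, end, length(sizes),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts_rel, collapse = ","), ","))
}

# random coverage vectors with occasional sparsity, for property tests
random_coverage <- function(n = 100, seed = 20260919) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    L <- sample(2:500, 1)
    d <- rpois(L, lambda = sample(c(0.2, 1, 5), 1))
    if (sum(d) == 0) d[sample(L, 1)] <- 1
    as.numeric(d)
  })
}

# minimal clear_result stub for selection tests
stub_result <- function(sample_id, ranked_ids, pass_n, undefined_ids = character()) {
  n <- length(ranked_ids)
  records <- data.table::data.table(
    transcript_id = c(ranked_ids, undefined_ids),
    gene_id = c(ranked_ids, undefined_ids),
    rank = c(seq_len(n), rep(NA_integer_, length(undefined_ids))),
    norm_expression = c(rev(seq_len(n)) * 10, rep(0, length(undefined_ids))),
    mu = c(rep(0, n), rep(NA_real_, length(undefined_ids))),
    pass = c(seq_len(n) <= pass_n, rep(FALSE, length(undefined_ids))))
  structure(list(sample_id = sample_id, records = records,
                 ranked = records[!is.na(rank)],
                 windows = NULL, cutoff = NULL, config = NULL,
                 expression_source = "stub", warnings = character(),
                 inputs = list()),
            class = "clear_result")
}

bin_centers <- function(n_bins = 25L) {
  edges <- seq(-1, 1, length.out = n_bins + 1L)
  (edges[-1] + edges[-(n_bins + 1L)]) / 2
}
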