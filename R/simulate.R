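#' Specification for a synthetic limiting-cell RNA-seq sample
#'
#' The generator emulates the coverage regimes seen in low-input
#' libraries: transcripts above a noise-onset expression rank receive
#' near-uniform positional read placement; below it, reads pile up
#' toward one transcript end (positional Beta law, a 3'- or 5'-biased
#' side chosen per transcript) or the transcript drops out entirely.
#' Genes are tiled with intron gaps on one synthetic chromosome so the
#' full genomic code path — BedGraph parsing, exon projection, intron
#' exclusion, strand reversal — is exercised, not just in-memory
#' vectors.
#'
#' Defaults describe the validation conditions used throughout the
#' package: 7,000 genes, noise onset at rank 2,000, an equal mixture of
#' Beta(5,1) (3'-skew) and Beta(1,5) (5'-skew) positional laws below
#' the onset, 20% dropout, log-normal expression.
#'
#' @param n_genes number of genes (one transcript each).
#' @param length_range min/max exonic transcript length (nt).
#' @param n_exons_range min/max exons per transcript.
#' @param intron_length intron size between exons (nt).
#' @param gap intergenic gap on the synthetic chromosome (nt).
#' @param expr_meanlog,expr_sdlog log-normal law of the per-kilobase
#'   expression level.
#' @param bias_onset_rank expression rank (1 = highest) below which
#'   coverage becomes positionally biased.
#' @param bias_shape two Beta shape parameters of the skewed positional
#'   law, oriented toward the 3' end; the 5'-biased side uses the
#'   mirrored law.
#' @param bias_mix fraction of biased transcripts skewed toward 3'.
#' @param dropout_rate fraction of below-onset transcripts forced to
#'   zero coverage.
#' @param depth_scale expected reads per (per-kb expression unit x kb).
#' @param read_length read span (nt), clipped at transcript ends.
#' @param minus_strand_prob probability a gene is on the minus strand.
#' @param chrom synthetic chromosome name.
#' @param seed integer seed; mandatory, all outputs are reproducible
#'   from it.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(n_genes = 7000L, length_range = c(1000L, 4000L),
                     n_exons_range = c(1L, 4L), intron_length = 300L,
                     gap = 500L, expr_meanlog = log(25), expr_sdlog = 2,
                     bias_onset_rank = 2000L, bias_shape = c(5, 1),
                     bias_mix = 0.5, dropout_rate = 0.2,
                     depth_scale = 0.4, read_length = 100L,
                     minus_strand_prob = 0.5, chrom = "chrS", seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("a scalar integer seed is required")
  spec <- list(n_genes = as.integer(n_genes),
               length_range = as.integer(length_range),
               n_exons_range = as.integer(n_exons_range),
               intron_length = as.integer(intron_length),
               gap = as.integer(gap),
               expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
               bias_onset_rank = as.integer(bias_onset_rank),
               bias_shape = bias_shape, bias_mix = bias_mix,
               dropout_rate = dropout_rate, depth_scale = depth_scale,
               read_length = as.integer(read_length),
               minus_strand_prob = minus_strand_prob,
               chrom = chrom, seed = as.integer(seed))
  with(spec, stopifnot(
    n_genes >= 1, length_range[1] >= 10, length_range[2] >= length_range[1],
    n_exons_range[1] >= 1, n_exons_range[2] >= n_exons_range[1],
    intron_length >= 1, gap >= 1,
    bias_onset_rank >= 0, bias_onset_rank <= n_genes,
    all(bias_shape > 0), bias_mix >= 0, bias_mix <= 1,
    dropout_rate >= 0, dropout_rate <= 1,
    depth_scale > 0, read_length >= 1,
    minus_strand_prob >= 0, minus_strand_prob <= 1))
  class(spec) <- "sim_spec"
  spec
}

#' Simulate a synthetic sample
#'
#' Draws transcript structures, expression levels and read placements
#' according to a [sim_spec()].  Reads are placed positionally: each
#' read's center position along the transcript is drawn from the
#' regime's law (uniform above the onset rank, skewed Beta below) and
#' the read contributes +1 depth over a `read_length` span clipped to
#' the transcript.  Identical spec and seed give identical output.
#'
#' @param spec `sim_spec`.
#' @return list of class `clear_sim`: `spec`, `transcripts`
#'   (`clear_transcripts` layout), `truth` (per gene: `regime` —
#'   `"uniform"`, `"bias3"`, `"bias5"` or `"dropout"` — true rank,
#'   abundance, read count), `reads` (`data.table` of transcript-space
#'   half-open read intervals), `gene_map`.
#' @export
simulate_clear_data <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n <- spec$n_genes
  gene_id <- sprintf("SIMG%05d", seq_len(n))
  transcript_id <- sprintf("SIMT%05d", seq_len(n))

  L <- floor(runif(n, spec$length_range[1], spec$length_range[2] + 1))
  n_ex <- floor(runif(n, spec$n_exons_range[1], spec$n_exons_range[2] + 1))
  strand <- ifelse(runif(n) < spec$minus_strand_prob, "-", "+")

  # split each transcript into exon widths (each >= 1)
  exon_widths <- lapply(seq_len(n), function(i) {
    k <- n_ex[i]
    if (k == 1) return(L[i])
    cuts <- sort(sample.int(L[i] - 1L, k - 1L))
    diff(c(0L, cuts, L[i]))
  })
  # tile genes along the chromosome
  span <- vapply(exon_widths, function(w)
    sum(w) + (length(w) - 1L) * spec$intron_length, numeric(1))
  gstart <- cumsum(c(spec$gap, head(span + spec$gap, -1L)))
  exon_starts <- vector("list", n); exon_ends <- vector("list", n)
  for (i in seq_len(n)) {
    w <- exon_widths[[i]]
    es <- gstart[i] + cumsum(c(0L, head(w, -1L) + spec$intron_length))
    exon_starts[[i]] <- as.integer(es)
    exon_ends[[i]] <- as.integer(es + w)
  }
  transcripts <- data.table(transcript_id = transcript_id, gene_id = gene_id,
                            chrom = spec$chrom, strand = strand,
                            length_L = as.integer(L),
                            exon_starts = exon_starts, exon_ends = exon_ends)
  setattr(transcripts, "class", c("clear_transcripts", class(transcripts)))

  # expression and regimes (regime follows the true per-kb abundance rank)
  abundance <- rlnorm(n, spec$expr_meanlog, spec$expr_sdlog)
  rank_true <- frank(-abundance, ties.method = "first")
  regime <- rep("uniform", n)
  below <- rank_true > spec$bias_onset_rank
  u_drop <- runif(n); u_side <- runif(n)
  regime[below & u_drop < spec$dropout_rate] <- "dropout"
  still <- below & regime != "dropout"
  regime[still & u_side < spec$bias_mix] <- "bias3"
  regime[still & u_side >= spec$bias_mix] <- "bias5"

  n_reads <- rpois(n, abundance * (L / 1000) * spec$depth_scale)
  n_reads[regime == "dropout"] <- 0L

  gi <- rep.int(seq_len(n), n_reads)
  reg <- regime[gi]
  p <- numeric(length(gi))
  p[reg == "uniform"] <- runif(sum(reg == "uniform"))
  p[reg == "bias3"] <- rbeta(sum(reg == "bias3"),
                             spec$bias_shape[1], spec$bias_shape[2])
  p[reg == "bias5"] <- rbeta(sum(reg == "bias5"),
                             spec$bias_shape[2], spec$bias_shape[1])
  Lg <- L[gi]
  ctr <- round(p * (Lg - 1))
  s <- pmax(0, ctr - spec$read_length %/% 2L)
  e <- pmin(Lg, s + spec$read_length)
  reads <- data.table(gene_idx = gi, start = as.integer(s), end = as.integer(e))

  truth <- data.table(gene_id = gene_id, transcript_id = transcript_id,
                      length_L = as.integer(L), strand = strand,
                      abundance = abundance, rank_true = rank_true,
                      regime = regime, n_reads = as.integer(n_reads))

  structure(list(spec = spec, transcripts = transcripts, truth = truth,
                 reads = reads,
                 gene_map = data.table(transcript_id = transcript_id,
                                       gene_id = gene_id)),
            class = "clear_sim")
}

#' Exact mu and expression of a simulated sample
#'
#' Computes each transcript's mu directly from the read intervals via
#' the closed-form sums \eqn{\sum_k k d_k = \sum_r (s_r+e_r-1)(e_r-s_r)/2}
#' and \eqn{\sum_k d_k = \sum_r (e_r-s_r)}; identical to building the
#' per-base vector and calling [compute_mu()], but without
#' materialising depth vectors.  Expression is the simulated read
#' count per kilobase (what a counts table would yield).
#'
#' @param sim `clear_sim`.
#' @return `data.table`: `transcript_id`, `gene_id`, `mu`,
#'   `norm_expression`, plus truth columns for convenience.
#' @export
sim_mu <- function(sim) {
  agg <- sim$reads[, .(
    sum_kd = sum((start + end - 1) * (end - start) / 2),
    sum_d = sum(as.numeric(end - start))), by = gene_idx]
  out <- copy(sim$truth)
  out[, mu := NA_real_]
  out[agg$gene_idx, mu := (2 / length_L) * (agg$sum_kd / agg$sum_d) - 1]
  out[n_reads == 0L, mu := NA_real_]
  out[, norm_expression := n_reads / (length_L / 1000)]
  out[]
}

#' Per-base depth vector of one simulated transcript
#'
#' @param sim `clear_sim`.
#' @param transcript_id transcript to materialise.
#' @return numeric depth vector in transcript coordinates.
#' @export
sim_transcript_coverage <- function(sim, transcript_id) {
  i <- match(transcript_id, sim$truth$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", transcript_id)
  L <- sim$truth$length_L[i]
  rd <- sim$reads[gene_idx == i & end > start]
  if (!nrow(rd)) return(numeric(L))
  as.numeric(IRanges::coverage(IRanges::IRanges(start = rd$start + 1L,
                                                end = rd$end),
                               width = L))
}

#' Write a simulated sample to disk in the formats the readers consume
#'
#' Emits `annotation.bed` (BED12), `gene_map.tsv`, `<sample>.bedgraph`
#' (split-mode style: intronic and uncovered bases omitted),
#' `counts.tsv` (featureCounts layout) and `truth.tsv`.  Output is
#' byte-identical across runs for the same `clear_sim`.
#'
#' @param sim `clear_sim`.
#' @param dir output directory (created if needed).
#' @param sample_id sample column name for the counts table and the
#'   BedGraph file stem.
#' @return invisibly, named vector of paths.
#' @export
write_sim <- function(sim, dir, sample_id = "sim1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- sim$transcripts
  n <- nrow(tx)

  bed <- vapply(seq_len(n), function(i) {
    es <- tx$exon_starts[[i]]; ee <- tx$exon_ends[[i]]
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            tx$chrom[i], es[1], ee[length(ee)], tx$transcript_id[i],
            tx$strand[i], es[1], ee[length(ee)], length(es),
            paste0(paste(ee - es, collapse = ","), ","),
            paste0(paste(es - es[1], collapse = ","), ","))
  }, character(1))
  anno_path <- file.path(dir, "annotation.bed")
  writeLines(bed, anno_path)

  map_path <- file.path(dir, "gene_map.tsv")
  fwrite(sim$gene_map, map_path, sep = "\t", quote = FALSE)

  # genes are tiled without overlap, so genomic BedGraph intervals can be
  # emitted gene by gene in coordinate order
  reads_by_gene <- split(sim$reads, by = "gene_idx", keep.by = FALSE)
  lines <- vector("list", n)
  for (i in seq_len(n)) {
    rd <- reads_by_gene[[as.character(i)]]
    if (is.null(rd) || !nrow(rd)) next
    L <- tx$length_L[i]
    d <- as.numeric(IRanges::coverage(
      IRanges::IRanges(start = rd$start + 1L, end = rd$end), width = L))
    if (tx$strand[i] == "-") d <- rev(d)  # back to genomic orientation
    es <- tx$exon_starts[[i]]; ee <- tx$exon_ends[[i]]
    off <- cumsum(c(0L, head(ee - es, -1L)))
    gene_lines <- lapply(seq_along(es), function(j) {
      seg <- d[(off[j] + 1L):(off[j] + (ee[j] - es[j]))]
      r <- rle(seg)
      run_end <- cumsum(r$lengths)
      keep <- r$values > 0
      if (!any(keep)) return(character())
      sprintf("%s\t%d\t%d\t%g", sim$spec$chrom,
              es[j] + (run_end - r$lengths)[keep], es[j] + run_end[keep],
              r$values[keep])
    })
    lines[[i]] <- unlist(gene_lines)
  }
  bg_path <- file.path(dir, paste0(sample_id, ".bedgraph"))
  writeLines(unlist(lines), bg_path)

  counts_path <- file.path(dir, "counts.tsv")
  header <- paste("Geneid", "Chr", "Start", "End", "Strand", "Length",
                  sample_id, sep = "\t")
  rows <- sprintf("%s\t%s\t%d\t%d\t%s\t%d\t%d",
                  tx$gene_id, tx$chrom,
                  vapply(tx$exon_starts, `[`, integer(1), 1L),
                  vapply(tx$exon_ends, function(x) x[length(x)], integer(1)),
                  tx$strand, tx$length_L, sim$truth$n_reads)
  writeLines(c("# Program:clearseq simulate", header, rows), counts_path)

  truth_path <- file.path(dir, "truth.tsv")
  fwrite(sim$truth, truth_path, sep = "\t", quote = FALSE)

  invisible(c(annotation = anno_path, gene_map = map_path,
              bedgraph = bg_path, counts = counts_path, truth = truth_path))
}

#' Hand-computable six-gene worked example
#'
#' A deterministic fixture small enough to verify by arithmetic, used
#' in the unit tests and the tutorial.  Genes on `chrT`:
#' \describe{
#'   \item{WET1 (+, L=100)}{depth 10 on the TSS base only: mu = -1.}
#'   \item{WET2 (+, L=100)}{uniform depth 5: mu = -1/L = -0.01.}
#'   \item{WET3 (+, 2 exons, L=100)}{depth 8 inside the intron (never
#'     counted) and nothing exonic: mu undefined.}
#'   \item{WET4 (-, L=100)}{depth 7 on its highest-coordinate exonic
#'     base, which is the TSS of a minus-strand gene: mu = -1.}
#'   \item{WET5 (+, L=100)}{depth 1 over the 5' half, 3 over the 3'
#'     half: mu = 0.24.}
#'   \item{WET6 (-, L=100)}{same genomic depth pattern as WET5 on the
#'     minus strand, so its d is WET5's reversed: mu = -0.24 - 2/100 =
#'     -0.26 (the antisymmetry identity).}
#' }
#'
#' @return list: `annotation`, `bedgraph`, `counts` (text lines),
#'   `gene_map`, `truth` (`data.table` with exact expected `mu` and
#'   expected `pass`).
#' @export
make_worked_example <- function() {
  annotation <- c(
    "chrT\t100\t200\tWET1\t0\t+\t100\t200\t0\t1\t100,\t0,",
    "chrT\t400\t500\tWET2\t0\t+\t400\t500\t0\t1\t100,\t0,",
    "chrT\t700\t850\tWET3\t0\t+\t700\t850\t0\t2\t50,50,\t0,100,",
    "chrT\t1100\t1200\tWET4\t0\t-\t1100\t1200\t0\t1\t100,\t0,",
    "chrT\t1400\t1500\tWET5\t0\t+\t1400\t1500\t0\t1\t100,\t0,",
    "chrT\t1700\t1800\tWET6\t0\t-\t1700\t1800\t0\t1\t100,\t0,")
  bedgraph <- c(
    "chrT\t100\t101\t10",
    "chrT\t400\t500\t5",
    "chrT\t760\t790\t8",
    "chrT\t1199\t1200\t7",
    "chrT\t1400\t1450\t1",
    "chrT\t1450\t1500\t3",
    "chrT\t1700\t1750\t1",
    "chrT\t1750\t1800\t3")
  counts <- c(
    "# Program:clearseq worked example",
    paste("Geneid", "Chr", "Start", "End", "Strand", "Length", "wex1",
          sep = "\t"),
    "WEG1\tchrT\t100\t200\t+\t100\t50",
    "WEG2\tchrT\t400\t500\t+\t100\t500",
    "WEG3\tchrT\t700\t850\t+\t100\t40",
    "WEG4\tchrT\t1100\t1200\t-\t100\t70",
    "WEG5\tchrT\t1400\t1500\t+\t100\t200",
    "WEG6\tchrT\t1700\t1800\t-\t100\t200")
  gene_map <- data.table(
    transcript_id = paste0("WET", 1:6),
    gene_id = paste0("WEG", 1:6))
  truth <- data.table(
    transcript_id = paste0("WET", 1:6),
    gene_id = paste0("WEG", 1:6),
    length_L = 100L,
    mu = c(-1, -0.01, NA_real_, -1, 0.24, -0.26),
    raw_count = c(50, 500, 40, 70, 200, 200),
    pass = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  list(annotation = annotation, bedgraph = bedgraph, counts = counts,
       gene_map = gene_map, truth = truth)
}

#' Write the worked example to a directory
#'
#' @param dir output directory.
#' @return invisibly, named vector of paths.
#' @export
write_worked_example <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wex <- make_worked_example()
  paths <- c(annotation = file.path(dir, "annotation.bed"),
             bedgraph = file.path(dir, "wex1.bedgraph"),
             counts = file.path(dir, "counts.tsv"),
             gene_map = file.path(dir, "gene_map.tsv"),
             truth = file.path(dir, "truth.tsv"))
  writeLines(wex$annotation, paths["annotation"])
  writeLines(wex$bedgraph, paths["bedgraph"])
  writeLines(wex$counts, paths["counts"])
  fwrite(wex$gene_map, paths["gene_map"], sep = "\t", quote = FALSE)
  fwrite(wex$truth, paths["truth"], sep = "\t", quote = FALSE)
  invisible(paths)
}
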