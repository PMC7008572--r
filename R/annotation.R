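#' Load transcript models from BED12 or genePred annotation
#'
#' Reads an annotation file, validates the exon block structure and
#' reduces every gene to a single representative transcript: the one
#' with the largest total exonic length.  Ties are broken
#' deterministically by keeping the lexicographically smallest
#' transcript identifier.  All coordinates are kept 0-based half-open
#' (BedGraph-compatible).
#'
#' Supported dialects:
#' \describe{
#'   \item{`bed12`}{UCSC 12-column BED with `blockSizes`/`blockStarts`.
#'     The `name` field is the transcript id; the gene id is taken from
#'     `gene_map` when given, otherwise it defaults to the transcript
#'     id (one gene per record).}
#'   \item{`genepred`}{UCSC table dumps: refFlat (gene symbol in column
#'     1) or extended genePred (`name2` in column 12).  Standard
#'     10-column genePred has no gene column; the transcript id is used.}
#' }
#'
#' @param path annotation file.
#' @param format `"auto"` (default), `"bed12"` or `"genepred"`.
#' @param gene_map optional two-column data frame (`transcript_id`,
#'   `gene_id`) used to assign genes to BED12 records.
#' @return A `data.table` of class `clear_transcripts` with one row per
#'   gene: `transcript_id`, `gene_id`, `chrom`, `strand`, `length_L`,
#'   and list columns `exon_starts`/`exon_ends` (0-based half-open,
#'   ascending by genomic start).  The attribute `"log"` records counts
#'   of records read, rejected and collapsed.
#' @export
load_transcripts <- function(path, format = c("auto", "bed12", "genepred"),
                             gene_map = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no annotation records in ", path)

  if (format == "auto") format <- .sniff_annotation(lines[[1]])
  recs <- switch(format,
    bed12    = .parse_bed12(lines, line_no, gene_map),
    genepred = .parse_genepred(lines, line_no)
  )

  n_zero <- sum(recs$n_zero_exons)
  if (n_zero > 0) {
    bad <- recs[n_zero_exons > 0L, transcript_id]
    message("dropping ", length(bad), " record(s) with zero-length exons: ",
            paste(head(bad, 5), collapse = ", "),
            if (length(bad) > 5) ", ...")
    recs <- recs[n_zero_exons == 0L]
    if (!nrow(recs)) stop("all records rejected (zero-length exons)")
  }

  # longest isoform per gene; ties -> smallest transcript_id
  setorder(recs, gene_id, -length_L, transcript_id)
  n_isoforms <- nrow(recs)
  models <- recs[, .SD[1L], by = gene_id]
  setcolorder(models, c("transcript_id", "gene_id", "chrom", "strand",
                        "length_L", "exon_starts", "exon_ends"))
  models[, n_zero_exons := NULL]
  setorder(models, transcript_id)
  setattr(models, "log", list(
    n_records = n_isoforms + n_zero,
    n_rejected_zero_exon = n_zero,
    n_collapsed_isoforms = n_isoforms - nrow(models),
    format = format))
  setattr(models, "class", c("clear_transcripts", class(models)))
  models[]
}

.sniff_annotation <- function(line) {
  f <- strsplit(line, "\t| +")[[1]]
  # BED12: cols 2,3 numeric, col 6 strand, 12 columns with comma lists at 11,12
  if (length(f) >= 12 && !is.na(suppressWarnings(as.numeric(f[2]))) &&
      f[6] %in% c("+", "-")) return("bed12")
  if (length(f) >= 10 && (f[3] %in% c("+", "-") || f[4] %in% c("+", "-")))
    return("genepred")
  stop("cannot auto-detect annotation dialect; pass format= explicitly")
}

.split_fields <- function(lines) strsplit(lines, "\t")

.parse_int <- function(x, what, line_no) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop("malformed ", what, " at line ", line_no[bad[1]], ": '", x[bad[1]], "'")
  v
}

.parse_bed12 <- function(lines, line_no, gene_map) {
  fl <- .split_fields(lines)
  nf <- lengths(fl)
  if (any(nf < 12)) {
    i <- which(nf < 12)[1]
    stop("malformed BED12 record at line ", line_no[i],
         ": expected 12 fields, got ", nf[i])
  }
  m <- do.call(rbind, lapply(fl, `[`, 1:12))
  chrom  <- m[, 1]
  start  <- .parse_int(m[, 2], "chromStart", line_no)
  name   <- m[, 4]
  strand <- m[, 6]
  if (!all(strand %in% c("+", "-")))
    stop("malformed strand at line ", line_no[which(!strand %in% c("+", "-"))[1]])
  n_blocks <- .parse_int(m[, 10], "blockCount", line_no)

  parse_list <- function(s, what, i) {
    v <- suppressWarnings(as.integer(strsplit(sub(",$", "", s), ",")[[1]]))
    if (anyNA(v)) stop("malformed ", what, " at line ", line_no[i])
    v
  }
  recs <- lapply(seq_along(fl), function(i) {
    sizes  <- parse_list(m[i, 11], "blockSizes", i)
    starts <- parse_list(m[i, 12], "blockStarts", i)
    if (length(sizes) != n_blocks[i] || length(starts) != n_blocks[i])
      stop("block count mismatch at line ", line_no[i])
    es <- start[i] + starts
    ee <- es + sizes
    if (is.unsorted(es, strictly = TRUE) || any(ee[-length(ee)] > es[-1]))
      stop("overlapping or unsorted exon blocks at line ", line_no[i])
    list(transcript_id = name[i], chrom = chrom[i], strand = strand[i],
         exon_starts = list(es), exon_ends = list(ee),
         length_L = sum(sizes), n_zero_exons = sum(sizes <= 0L))
  })
  dt <- rbindlist(recs)
  if (is.null(gene_map)) {
    dt[, gene_id := transcript_id]
  } else {
    gm <- as.data.table(gene_map)
    setnames(gm, 1:2, c("transcript_id", "gene_id"))
    dt <- merge(dt, gm, by = "transcript_id", all.x = TRUE, sort = FALSE)
    dt[is.na(gene_id), gene_id := transcript_id]
  }
  dt
}

.parse_genepred <- function(lines, line_no) {
  fl <- .split_fields(lines)
  nf <- lengths(fl)
  if (any(nf < 10)) {
    i <- which(nf < 10)[1]
    stop("malformed genePred record at line ", line_no[i],
         ": expected >= 10 fields, got ", nf[i])
  }
  first <- fl[[1]]
  refflat <- first[4] %in% c("+", "-")   # refFlat: geneName, name, chrom, strand
  recs <- lapply(seq_along(fl), function(i) {
    f <- fl[[i]]
    if (refflat) {
      gene <- f[1]; tx <- f[2]; chrom <- f[3]; strand <- f[4]
      starts_s <- f[10]; ends_s <- f[11]
    } else {
      tx <- f[1]; chrom <- f[2]; strand <- f[3]
      starts_s <- f[9]; ends_s <- f[10]
      gene <- if (length(f) >= 12 && nzchar(f[12])) f[12] else tx
    }
    if (!strand %in% c("+", "-"))
      stop("malformed strand at line ", line_no[i])
    es <- suppressWarnings(as.integer(strsplit(sub(",$", "", starts_s), ",")[[1]]))
    ee <- suppressWarnings(as.integer(strsplit(sub(",$", "", ends_s), ",")[[1]]))
    if (anyNA(es) || anyNA(ee) || length(es) != length(ee) || !length(es))
      stop("malformed exon list at line ", line_no[i])
    if (any(ee < es) || is.unsorted(es, strictly = FALSE))
      stop("malformed exon intervals at line ", line_no[i])
    list(transcript_id = tx, gene_id = gene, chrom = chrom, strand = strand,
         exon_starts = list(es), exon_ends = list(ee),
         length_L = sum(ee - es), n_zero_exons = sum(ee - es <= 0L))
  })
  rbindlist(recs)
}

#' Read a featureCounts-style counts table
#'
#' Tolerates the leading `#` program comment line and the six annotation
#' columns (`Geneid`, `Chr`, `Start`, `End`, `Strand`, `Length`) before
#' the sample columns.  Plain two-column `gene<TAB>count` tables are
#' accepted too.
#'
#' @param path counts file (tab-separated).
#' @return `data.table` with `gene_id` followed by one numeric column
#'   per sample.
#' @export
read_feature_counts <- function(path) {
  dt <- tryCatch(
    fread(path, sep = "\t", header = TRUE, skip = "Geneid",
          blank.lines.skip = TRUE),
    error = function(e) NULL)
  if (is.null(dt) || !nrow(dt) || ncol(dt) < 2) {
    dt <- fread(path, sep = "\t", header = TRUE)
  }
  anno <- intersect(c("Chr", "Start", "End", "Strand", "Length"), names(dt))
  if (length(anno)) dt[, (anno) := NULL]
  setnames(dt, 1, "gene_id")
  num <- names(dt)[-1]
  dt[, (num) := lapply(.SD, as.numeric), .SDcols = num]
  dt[]
}

#' Attach gene-level expression to transcript models
#'
#' Joins a counts table onto transcript models by `gene_id` and derives
#' the length-normalized expression used for ranking: raw count divided
#' by exonic length in kilobases.  Genes present on only one side of the
#' join are dropped; their counts are recorded in the `"reconciliation"`
#' attribute so the loss is auditable.
#'
#' @param models `clear_transcripts` from [load_transcripts()].
#' @param counts data frame with a `gene_id` column and at least one
#'   numeric count column (e.g. from [read_feature_counts()]).
#' @param sample which count column to use; defaults to the first.
#' @return `data.table`: `gene_id`, `transcript_id`, `length_L`,
#'   `raw_count`, `norm_expression` (count per kb of `length_L`).
#' @export
attach_expression <- function(models, counts, sample = NULL) {
  cnt <- as.data.table(counts)
  if (!"gene_id" %in% names(cnt)) setnames(cnt, 1, "gene_id")
  if (anyDuplicated(cnt$gene_id)) {
    dup <- unique(cnt$gene_id[duplicated(cnt$gene_id)])
    stop("duplicate gene rows in counts table: ",
         paste(head(dup, 10), collapse = ", "))
  }
  if (is.null(sample)) sample <- setdiff(names(cnt), "gene_id")[1]
  if (is.na(sample) || !sample %in% names(cnt))
    stop("counts table has no usable sample column")
  cnt <- cnt[, .(gene_id, raw_count = as.numeric(get(sample)))]
  if (any(cnt$raw_count < 0, na.rm = TRUE)) stop("negative counts in table")

  mod <- as.data.table(models)[, .(gene_id, transcript_id, length_L)]
  joined <- merge(mod, cnt, by = "gene_id", sort = FALSE)
  joined[, norm_expression := raw_count / (length_L / 1000)]
  joined[raw_count == 0, norm_expression := 0]
  setorder(joined, transcript_id)
  setattr(joined, "reconciliation", list(
    n_counts_without_model = length(setdiff(cnt$gene_id, mod$gene_id)),
    n_models_without_counts = length(setdiff(mod$gene_id, cnt$gene_id)),
    n_joined = nrow(joined),
    sample = sample))
  joined[]
}
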