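#' Read a BedGraph coverage track
#'
#' Parses a UCSC 4-column BedGraph (0-based half-open intervals) into a
#' run-length encoded per-chromosome track.  `track`/`browser`/`#`
#' lines are skipped.  Positions absent from the file are depth 0,
#' which is the correct reading of split-mode `genomecov` output where
#' spliced-read gaps (introns) carry no coverage.
#'
#' Validation is strict: non-numeric coordinates or depth, `end <=
#' start`, negative depth and overlapping intervals within a chromosome
#' all raise an error naming the offending line.
#'
#' @param path BedGraph file.
#' @param aliases optional named character vector mapping file
#'   chromosome names to canonical names (e.g. `c("1" = "chr1")`).
#'   Without it chromosome names are taken verbatim; mismatches against
#'   the annotation surface later as all-zero projections, which
#'   [project_coverage()] reports.
#' @return object of class `clear_track`: a named list with one
#'   [S4Vectors::Rle] of depths per chromosome (length = last covered
#'   base).
#' @export
read_bedgraph <- function(path, aliases = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    track <- structure(list(), class = "clear_track")
    return(track)
  }
  dt <- tryCatch(
    fread(text = lines, header = FALSE, sep = "\t",
          colClasses = list(character = 1),
          col.names = c("chrom", "start", "end", "depth")),
    error = function(e) {
      # fall back to whitespace splitting for space-delimited files
      fl <- strsplit(trimws(lines), "[ \t]+")
      if (any(lengths(fl) != 4))
        stop("malformed BedGraph line ", line_no[which(lengths(fl) != 4)[1]],
             ": expected 4 fields", call. = FALSE)
      m <- do.call(rbind, fl)
      data.table(chrom = m[, 1],
                 start = suppressWarnings(as.numeric(m[, 2])),
                 end   = suppressWarnings(as.numeric(m[, 3])),
                 depth = suppressWarnings(as.numeric(m[, 4])))
    })
  dt[, start := suppressWarnings(as.numeric(start))]
  dt[, end   := suppressWarnings(as.numeric(end))]
  dt[, depth := suppressWarnings(as.numeric(depth))]
  bad <- which(is.na(dt$start) | is.na(dt$end) | is.na(dt$depth))
  if (length(bad))
    stop("non-numeric field in BedGraph at line ", line_no[bad[1]])
  bad <- which(dt$end <= dt$start)
  if (length(bad))
    stop("BedGraph interval with end <= start at line ", line_no[bad[1]])
  bad <- which(dt$depth < 0)
  if (length(bad))
    stop("negative depth in BedGraph at line ", line_no[bad[1]])

  if (!is.null(aliases)) {
    hit <- dt$chrom %in% names(aliases)
    dt[hit, chrom := aliases[chrom]]
  }
  dt[, orig := .I]
  setorder(dt, chrom, start)
  ov <- dt[, any(start[-1] < end[-.N]), by = chrom]
  if (any(ov$V1)) {
    ch <- ov$chrom[ov$V1][1]
    sub <- dt[chrom == ch]
    i <- which(sub$start[-1] < sub$end[-nrow(sub)])[1]
    stop("overlapping BedGraph intervals on ", ch, " at line ",
         line_no[sub$orig[i + 1L]])
  }

  track <- lapply(split(dt, by = "chrom", keep.by = FALSE), function(d) {
    # interleave zero gaps and covered runs into one Rle
    gap_before <- c(d$start[1], d$start[-1] - d$end[-nrow(d)])
    widths <- as.vector(rbind(gap_before, d$end - d$start))
    values <- as.vector(rbind(0, d$depth))
    nz <- widths > 0
    S4Vectors::Rle(values[nz], widths[nz])
  })
  structure(track, class = "clear_track")
}

#' @export
print.clear_track <- function(x, ...) {
  cat("clear_track:", length(x), "chromosome(s)\n")
  for (ch in names(x))
    cat("  ", ch, ": covered span ", length(x[[ch]]), " bp, total depth ",
        sum(as.numeric(S4Vectors::runValue(x[[ch]]) *
                         S4Vectors::runLength(x[[ch]]))), "\n", sep = "")
  invisible(x)
}

#' Project genomic coverage onto transcript coordinates
#'
#' For each transcript model, extracts the per-base depths of its
#' exonic positions and concatenates them 5' to 3' in transcript order:
#' ascending genomic order on the plus strand, reversed on the minus
#' strand, so index `k = 0` is always the transcription start site.
#' Intronic bases never contribute.  A transcript on a chromosome
#' absent from the track projects to an all-zero vector (counted in the
#' `"n_missing_chrom"` attribute rather than erroring, since a sparse
#' library legitimately covers few contigs).
#'
#' The track is run-length encoded, so projection never materialises
#' whole-genome per-base arrays.
#'
#' @param track `clear_track` from [read_bedgraph()].
#' @param transcripts `clear_transcripts` from [load_transcripts()], or
#'   any data frame with the same columns.
#' @return named list (by `transcript_id`) of numeric depth vectors
#'   `d`, each of length `length_L`; attribute `"n_missing_chrom"`
#'   counts transcripts whose chromosome was absent.
#' @export
project_coverage <- function(track, transcripts) {
  tx <- as.data.table(transcripts)
  missing_chrom <- 0L
  out <- vector("list", nrow(tx))
  names(out) <- tx$transcript_id
  for (i in seq_len(nrow(tx))) {
    es <- tx$exon_starts[[i]]
    ee <- tx$exon_ends[[i]]
    L <- sum(ee - es)
    rle <- track[[tx$chrom[i]]]
    if (is.null(rle)) {
      missing_chrom <- missing_chrom + 1L
      out[[i]] <- numeric(L)
      next
    }
    n <- length(rle)
    # clip exons to the covered span; bases beyond it are depth 0
    cs <- pmin(es, n); ce <- pmin(ee, n)
    w <- ce - cs
    d <- numeric(L)
    if (any(w > 0)) {
      ir <- IRanges::IRanges(start = cs[w > 0] + 1L, end = ce[w > 0])
      vals <- as.numeric(rle[ir])
      # scatter extracted runs back into the full-length vector
      offs <- cumsum(c(0L, (ee - es)[-length(es)]))
      idx <- unlist(lapply(which(w > 0), function(j)
        offs[j] + seq_len(w[j])), use.names = FALSE)
      d[idx] <- vals
    }
    if (tx$strand[i] == "-") d <- rev(d)
    out[[i]] <- d
  }
  attr(out, "n_missing_chrom") <- missing_chrom
  out
}
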