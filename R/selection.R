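#' Combine CLEAR results across samples
#'
#' A transcript enters the consensus when it passes CLEAR in at least
#' `min_samples` of the supplied samples.  The published default is the
#' strict intersection (`min_samples = `number of samples); lowering it
#' relaxes the inclusion criterion.  Output ordering is deterministic:
#' by the best (smallest) expression rank achieved across samples, ties
#' by transcript id.
#'
#' @param results list of `clear_result` objects (from [run_clear()]
#'   or [read_clear_result()]).
#' @param min_samples minimum number of samples a transcript must pass
#'   in; default all.
#' @return list of class `clear_cohort`: `consensus` (`data.table`
#'   with `transcript_id`, `n_pass`, `best_rank`), `matrix`
#'   (transcript x sample status table: `"pass"`, `"excluded"` — ranked
#'   but below cutoff — or `"undefined"` — no defined mu), `samples`,
#'   `min_samples`.
#' @export
intersect_clear <- function(results, min_samples = length(results)) {
  stopifnot(length(results) >= 1)
  if (!is.numeric(min_samples) || length(min_samples) != 1 ||
      min_samples < 1 || min_samples > length(results))
    stop("min_samples must be between 1 and the number of samples (",
         length(results), ")")
  min_samples <- as.integer(min_samples)
  ids <- lapply(results, function(r) r$sample_id)
  if (anyDuplicated(unlist(ids)))
    stop("duplicate sample_id among results")

  per_sample <- rbindlist(lapply(results, function(r) {
    data.table(sample_id = r$sample_id,
               transcript_id = r$records$transcript_id,
               rank = r$records$rank,
               status = ifelse(r$records$pass, "pass",
                               ifelse(is.na(r$records$mu), "undefined",
                                      "excluded")))
  }))

  status <- dcast(per_sample, transcript_id ~ sample_id,
                  value.var = "status", fill = "undefined")
  agg <- per_sample[, .(n_pass = sum(status == "pass"),
                        best_rank = suppressWarnings(
                          as.numeric(min(rank, na.rm = TRUE)))),
                    by = transcript_id]
  agg[!is.finite(best_rank), best_rank := NA_real_]
  consensus <- agg[n_pass >= min_samples]
  setorder(consensus, best_rank, transcript_id, na.last = TRUE)

  structure(list(consensus = consensus,
                 matrix = status,
                 samples = vapply(results, `[[`, "", "sample_id"),
                 min_samples = min_samples),
            class = "clear_cohort")
}

#' @export
print.clear_cohort <- function(x, ...) {
  cat("clear_cohort: ", length(x$samples), " sample(s), min_samples = ",
      x$min_samples, "\n  consensus transcripts: ", nrow(x$consensus),
      "\n", sep = "")
  invisible(x)
}

#' Conservative log2 fold-change bound at the CLEAR cutoff
#'
#' For a gene that passes CLEAR in one group but fails in the other, a
#' naive fold change against its unreliable low count is inflated by
#' dropouts.  Substituting the failing group's value with the cutoff
#' expression (the count of the lowest transcript passing CLEAR in that
#' sample) yields `log2(mean_count_high / cutoff_count)`, a bound the
#' data can actually support: any true failing-group expression below
#' the cutoff gives a larger ratio, so the bound is conservative.
#'
#' @param mean_count_high mean count in the passing (high) group; > 0.
#' @param cutoff_count cutoff expression of the failing sample; > 0.
#' @return log2 bound (scalar or vector).
#' @export
fold_change_bound <- function(mean_count_high, cutoff_count) {
  if (any(!is.finite(mean_count_high)) || any(!is.finite(cutoff_count)) ||
      any(mean_count_high <= 0) || any(cutoff_count <= 0))
    stop("fold_change_bound requires positive, finite inputs")
  log2(mean_count_high / cutoff_count)
}

#' Write cohort selection reports
#'
#' Emits three files into `dir`:
#' \describe{
#'   \item{`consensus.tsv`}{the analysis-ready transcript whitelist
#'     (`transcript_id`, `n_pass`, `best_rank`), consumable by
#'     downstream DEG tools.}
#'   \item{`matrix.tsv`}{per-transcript pass/fail matrix: one logical
#'     `<sample>` column per sample plus a `<sample>_status` column
#'     distinguishing `"excluded"` (fitted but below cutoff) from
#'     `"undefined"` (no defined mu).}
#'   \item{`summary.json`}{per-sample pass counts and the consensus
#'     count.}
#' }
#'
#' @param cohort `clear_cohort` from [intersect_clear()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_clear_report <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cons_path <- file.path(dir, "consensus.tsv")
  mat_path <- file.path(dir, "matrix.tsv")
  sum_path <- file.path(dir, "summary.json")

  fwrite(cohort$consensus, cons_path, sep = "\t", na = "NA", quote = FALSE)

  mat <- copy(cohort$matrix)
  for (s in cohort$samples) {
    set(mat, j = paste0(s, "_status"), value = mat[[s]])
    set(mat, j = s, value = mat[[s]] == "pass")
  }
  setcolorder(mat, c("transcript_id", cohort$samples,
                     paste0(cohort$samples, "_status")))
  setorder(mat, transcript_id)
  fwrite(mat, mat_path, sep = "\t", na = "NA", quote = FALSE)

  pass_counts <- lapply(cohort$samples, function(s)
    sum(cohort$matrix[[s]] == "pass"))
  names(pass_counts) <- cohort$samples
  jsonlite::write_json(list(samples = as.list(pass_counts),
                            min_samples = cohort$min_samples,
                            consensus_count = nrow(cohort$consensus)),
                       sum_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(consensus = cons_path, matrix = mat_path, summary = sum_path))
}
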