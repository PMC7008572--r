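#' Positional-skew statistic mu of a coverage vector
#'
#' Maps the mean read position along a transcript onto \[-1, 1\]:
#' \deqn{\mu = \frac{2}{L}\,\frac{\sum_{k=0}^{L-1} k\,d_k}
#'                         {\sum_{k=0}^{L-1} d_k} - 1}
#' where `d_k` is the depth at exonic position `k`, zero-indexed at the
#' transcription start site.  All coverage at the 5' base gives
#' `mu = -1`; all at the 3' base gives `1 - 2/L`; uniform coverage
#' gives `-1/L`.  With zero total coverage mu is undefined and
#' `NA_real_` is returned (a first-class "undefined", not an error).
#'
#' @param d numeric vector of non-negative depths, length `L >= 1`.
#' @return scalar mu in `[-1, 1 - 2/L]`, or `NA_real_`.
#' @export
compute_mu <- function(d) {
  L <- length(d)
  if (L < 1) stop("empty coverage vector")
  s <- sum(d)
  if (s <= 0) return(NA_real_)
  (2 / L) * (sum((seq_len(L) - 1) * d) / s) - 1
}

#' mu for every transcript of a projected sample
#'
#' @param coverages named list of depth vectors from
#'   [project_coverage()].
#' @return `data.table`: `transcript_id`, `mu` (`NA` when total
#'   coverage is zero), `total` (sum of depths), `coverage_per_base`
#'   (total / length, the coverage-derived expression fallback).
#' @export
mu_table <- function(coverages) {
  dt <- data.table(
    transcript_id = names(coverages),
    mu = vapply(coverages, compute_mu, numeric(1)),
    total = vapply(coverages, sum, numeric(1)),
    length_L = lengths(coverages))
  dt[, coverage_per_base := total / length_L]
  dt[]
}

#' Rank transcripts by length-normalized expression
#'
#' Orders records by descending `norm_expression`, breaking ties by
#' ascending `transcript_id`, and assigns 1-based ranks (1 = highest
#' expression).  Transcripts with undefined mu (zero coverage) or zero
#' expression cannot participate in window fitting; they are returned
#' separately in the `"excluded"` attribute rather than silently
#' dropped.
#'
#' @param records data frame with `transcript_id`, `mu`,
#'   `norm_expression` (plus any carried columns).
#' @return ranked `data.table` with a `rank` column; attribute
#'   `"excluded"` holds the removed records.
#' @export
rank_transcripts <- function(records) {
  dt <- as.data.table(records)
  stopifnot(all(c("transcript_id", "mu", "norm_expression") %in% names(dt)))
  drop <- is.na(dt$mu) | dt$norm_expression <= 0
  excluded <- dt[drop]
  ranked <- dt[!drop]
  setorder(ranked, -norm_expression, transcript_id)
  ranked[, rank := .I]
  setattr(ranked, "excluded", excluded)
  ranked[]
}
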