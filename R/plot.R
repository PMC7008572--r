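#' Per-window summary statistics of mu
#'
#' The numbers behind the violin plot: for every full window of the
#' expression ranking (whether or not the cutoff scan fitted it), the
#' mean and extrema of mu.  Tests assert on these instead of rendered
#' pixels.
#'
#' @param result `clear_result` from [run_clear()] (needs the ranked
#'   records and config).
#' @return `data.table`: `window_index`, `start_rank`, `end_rank`,
#'   `mean_mu`, `min_mu`, `max_mu`.
#' @export
mu_window_stats <- function(result) {
  if (is.null(result$config))
    stop("result lacks a config (was it read back from a TSV?); ",
         "window statistics need the full run_clear() output")
  ranked <- result$ranked
  size <- result$config$window_size
  step <- result$config$window_step
  n <- nrow(ranked)
  n_windows <- if (n >= size) (n - size) %/% step + 1L else 0L
  if (n_windows == 0L) stop("no full windows (", n, " ranked transcripts)")
  rbindlist(lapply(seq_len(n_windows), function(w) {
    idx <- ((w - 1L) * step + 1L):((w - 1L) * step + size)
    data.table(window_index = w, start_rank = idx[1], end_rank = idx[size],
               mean_mu = mean(ranked$mu[idx]),
               min_mu = min(ranked$mu[idx]),
               max_mu = max(ranked$mu[idx]))
  }))
}

#' QC plots of the mu distribution
#'
#' Two views of a sample's CLEAR scan, mirroring the standard QC
#' figures for the method:
#' \describe{
#'   \item{violin}{one violin of mu values per expression-ranked
#'     window, with end marks at the window extrema and a middle bar at
#'     the mean.  With many windows only every `m`-th is drawn so at
#'     most `max_violins` render; `m` is recorded in the plot subtitle
#'     and returned attribute.}
#'   \item{scatter}{mu against expression rank, with a vertical red
#'     line at the detected cutoff rank (omitted when no cutoff
#'     triggered).}
#' }
#'
#' @param result `clear_result`.
#' @param kind `"violin"` or `"scatter"`.
#' @param path optional output stem; when given the figure is written
#'   as both `<path>.pdf` (vector) and `<path>.png` (raster).
#' @param max_violins cap on rendered violins.
#' @param max_rank truncate the scatter at this rank (`Inf` to
#'   disable); defaults to the top 7,000 transcripts for readability.
#' @return the ggplot object, invisibly; attribute `"downsample"`
#'   holds `m` for violin plots.
#' @export
plot_mu <- function(result, kind = c("violin", "scatter"), path = NULL,
                    max_violins = 100L, max_rank = 7000) {
  kind <- match.arg(kind)
  ranked <- result$ranked
  if (is.null(ranked) || !nrow(ranked)) stop("no ranked transcripts to plot")

  if (kind == "violin") {
    stats <- mu_window_stats(result)  # errors informatively if no windows
    size <- result$config$window_size
    step <- result$config$window_step
    m <- max(1L, ceiling(nrow(stats) / max_violins))
    keep <- stats[seq(1L, nrow(stats), by = m)]
    dat <- rbindlist(lapply(seq_len(nrow(keep)), function(j) {
      idx <- keep$start_rank[j]:keep$end_rank[j]
      data.table(start_rank = keep$start_rank[j], mu = ranked$mu[idx])
    }))
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = factor(start_rank), y = mu)) +
      ggplot2::geom_violin(scale = "width", fill = "grey80", colour = "grey40") +
      ggplot2::stat_summary(fun = min, geom = "point", shape = 95, size = 3) +
      ggplot2::stat_summary(fun = max, geom = "point", shape = 95, size = 3) +
      ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.6,
                            linewidth = 0.3, colour = "black") +
      ggplot2::scale_x_discrete(breaks = function(x)
        x[seq(1, length(x), length.out = min(10, length(x)))]) +
      ggplot2::labs(x = "window start rank", y = expression(mu),
                    title = paste0("mu by expression-ranked window - ",
                                   result$sample_id),
                    subtitle = sprintf("windows of %d, step %d; every %d-th window shown",
                                       size, step, m)) +
      ggplot2::ylim(-1, 1) +
      ggplot2::theme_bw()
    attr(p, "downsample") <- m
  } else {
    dat <- ranked[rank <= max_rank]
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = rank, y = mu)) +
      ggplot2::geom_point(size = 0.3, alpha = 0.4) +
      ggplot2::labs(x = "expression rank", y = expression(mu),
                    title = paste0("mu vs expression rank - ",
                                   result$sample_id)) +
      ggplot2::ylim(-1, 1) +
      ggplot2::theme_bw()
    if (!is.null(result$cutoff))
      p <- p + ggplot2::geom_vline(xintercept = result$cutoff$rank,
                                   colour = "red")
  }

  if (!is.null(path)) {
    ggplot2::ggsave(paste0(path, ".pdf"), p, width = 8, height = 4.5)
    grDevices::png(paste0(path, ".png"), width = 1200, height = 675, res = 150)
    print(p)
    grDevices::dev.off()
  }
  invisible(p)
}
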