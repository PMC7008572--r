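#' Configuration for the CLEAR cutoff scan
#'
#' Defaults follow the published procedure: windows of 250 transcripts
#' advanced by 10, trigger when a fitted shape parameter exceeds 2.
#' The histogram bin count (25 equal-width bins on \[-1,1\], bin width
#' 0.08, ~10 expected counts per bin at the default window size) and
#' the treatment of the normalization constant are implementation
#' choices, both configurable.
#'
#' @param window_size transcripts per window.
#' @param window_step ranks the window advances by.
#' @param param_threshold bimodality trigger on the fitted `a` or `b`.
#' @param n_bins histogram bins over `[-1, 1]`.
#' @param fit_H if `TRUE` the normalization `H` is fitted (bounded
#'   positive); by default it is fixed at `window_size * bin_width / 4`
#'   because each mixture component integrates to 2 over `[-1, 1]`, so
#'   the bracket integrates to 4 and this choice makes expected counts
#'   sum to the window size.
#' @param param_upper practical optimizer bound on `a`, `b`.
#' @return list of class `clear_config`.
#' @export
clear_config <- function(window_size = 250L, window_step = 10L,
                         param_threshold = 2, n_bins = 25L,
                         fit_H = FALSE, param_upper = 100) {
  stopifnot(window_size >= 1, window_step >= 1,
            window_step <= window_size, n_bins >= 3,
            param_threshold > 0, param_upper > param_threshold)
  structure(list(window_size = as.integer(window_size),
                 window_step = as.integer(window_step),
                 param_threshold = param_threshold,
                 n_bins = as.integer(n_bins),
                 fit_H = isTRUE(fit_H),
                 param_upper = param_upper),
            class = "clear_config")
}

#' Double-beta mixture expected count
#'
#' Evaluates
#' \deqn{H\left[\frac{(1+x)\,(1-\tfrac12(1+x))^{1+b}}{2B(2,2+b)} +
#'       \frac{(1+x)^{1+a}\,(1-\tfrac12(1+x))}{2^{1+a}B(2+a,2)}\right]}
#' at bin location(s) `x` in `(-1, 1)`, where `B` is the beta integral.
#' In `u = (1+x)/2` the two bracket terms are mirrored Beta(2, 2+b) and
#' Beta(2+a, 2) densities: `a = b = 0` is a symmetric hump and growing
#' `a` (resp. `b`) pushes mass toward `+1` (resp. `-1`), so large
#' values flag a bimodal mu distribution.
#'
#' @param x numeric vector of bin centers, `|x| < 1`.
#' @param a,b non-negative shape parameters.
#' @param H normalization (fixed by the binning, or fitted).
#' @return expected counts, same length as `x`.
#' @export
eval_double_beta <- function(x, a, b, H = 1) {
  if (any(abs(x) >= 1)) stop("bin locations must satisfy |x| < 1")
  if (a < 0 || b < 0) stop("shape parameters must be non-negative")
  u <- (1 + x) / 2
  neg <- (1 + x) * (1 - u)^(1 + b) / (2 * beta(2, 2 + b))
  pos <- (1 + x)^(1 + a) * (1 - u) / (2^(1 + a) * beta(2 + a, 2))
  H * (neg + pos)
}

#' Histogram of mu values on [-1, 1]
#'
#' Equal-width bins; the lower edge of the first bin is closed so the
#' exact 5'-limit value `mu = -1` is counted.
#'
#' @param mu numeric vector in `[-1, 1]`.
#' @param n_bins number of bins.
#' @return list with `counts`, `centers`, `width`.
#' @export
mu_histogram <- function(mu, n_bins = 25L) {
  edges <- seq(-1, 1, length.out = n_bins + 1L)
  bin <- findInterval(mu, edges, rightmost.closed = TRUE, all.inside = TRUE)
  list(counts = tabulate(bin, nbins = n_bins),
       centers = (edges[-1] + edges[-(n_bins + 1L)]) / 2,
       width = 2 / n_bins)
}

#' Fit one window's mu histogram to the double-beta mixture
#'
#' Bound-constrained nonlinear least squares on the bin counts
#' (Levenberg-Marquardt with box bounds), with a multi-start grid over
#' `a, b` in `{0.1, 1, 5}` to escape local minima; the start with the
#' smallest residual sum of squares wins.  `a` and `b` are constrained
#' to `[0, param_upper]`, so fitted values are non-negative by
#' construction.  If no start converges the window is flagged
#' `converged = FALSE` with `NA` parameters; callers skip such windows
#' rather than treating them as triggering.
#'
#' @param mu vector of defined mu values (one window's worth).
#' @param config `clear_config`.
#' @return list of class `window_fit`: `a`, `b`, `H`, `converged`,
#'   `sse`, `n`, `histogram`.
#' @export
fit_window <- function(mu, config = clear_config()) {
  stopifnot(!anyNA(mu))
  h <- mu_histogram(mu, config$n_bins)
  fit <- fit_double_beta(h$counts, h$centers, h$width,
                         fit_H = config$fit_H,
                         param_upper = config$param_upper,
                         n_expected = config$window_size)
  fit$histogram <- h
  fit$n <- length(mu)
  class(fit) <- "window_fit"
  fit
}

#' Low-level double-beta histogram fit
#'
#' @param counts observed bin counts.
#' @param centers bin centers in `(-1, 1)`.
#' @param width bin width.
#' @param fit_H fit the normalization instead of fixing it.
#' @param param_upper upper box bound on `a`, `b`.
#' @param n_expected nominal window size used for the fixed `H`;
#'   defaults to `sum(counts)`.
#' @return list: `a`, `b`, `H`, `converged`, `sse`.
#' @export
fit_double_beta <- function(counts, centers, width, fit_H = FALSE,
                            param_upper = 100, n_expected = NULL) {
  if (is.null(n_expected)) n_expected <- sum(counts)
  H0 <- n_expected * width / 4
  starts <- expand.grid(a = c(0.1, 1, 5), b = c(0.1, 1, 5))
  resid_fn <- function(p) {
    H <- if (fit_H) p[3] else H0
    counts - eval_double_beta(centers, p[1], p[2], H)
  }
  lower <- c(0, 0); upper <- c(param_upper, param_upper)
  if (fit_H) { lower <- c(lower, 1e-8); upper <- c(upper, Inf) }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(starts$a[i], starts$b[i], if (fit_H) H0)
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res) || !res$info %in% 1:4) next
    sse <- sum(res$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = res$par, sse = sse)
  }
  if (is.null(best))
    return(list(a = NA_real_, b = NA_real_, H = NA_real_,
                converged = FALSE, sse = NA_real_))
  list(a = best$par[1], b = best$par[2],
       H = if (fit_H) best$par[3] else H0,
       converged = TRUE, sse = best$sse)
}

#' @export
print.window_fit <- function(x, ...) {
  cat(sprintf("window_fit: a = %.4g, b = %.4g, H = %.4g, converged = %s\n",
              x$a, x$b, x$H, x$converged))
  invisible(x)
}
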