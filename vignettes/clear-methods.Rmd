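---
title: "How clearseq decides which transcripts are reliably quantifiable"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How clearseq decides which transcripts are reliably quantifiable}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clearseq)
```

## The problem

Limiting-cell RNA-seq — full-length single-cell library chemistry applied to
tens or hundreds of cells — preamplifies tiny amounts of cDNA. At high
expression the resulting read coverage along a transcript looks like ordinary
bulk RNA-seq. At low expression it degenerates: PCR duplicates pile up in a
few spots, the rest of the gene body goes dark, and in other libraries the
same gene drops out entirely. Counts from this regime are not quantitative,
and differential-expression callers treat the pile-up-versus-dropout contrast
as huge fold changes. clearseq implements the CLEAR prefilter: find the
expression level where coverage stops being well behaved, and hand downstream
tools only the transcripts above it.

## The skew statistic mu

For each gene we use one representative transcript — the longest isoform, as
annotated — and its per-base exonic coverage `d_k`, with `k = 0` at the
transcription start site (minus-strand genes are reversed so this holds on
both strands; intronic bases are never counted, which is why split-mode
BedGraph input matters). The positional mean of the reads is rescaled to

$$\mu = \frac{2}{L}\,\frac{\sum_{k=0}^{L-1} k\,d_k}{\sum_{k=0}^{L-1} d_k} - 1$$

so that all coverage on the 5' base gives exactly $-1$, all coverage on the
3' base gives $1 - 2/L$, and uniform coverage gives $-1/L \approx 0$. The
statistic is invariant to depth scaling, and reversing a coverage vector
obeys the exact identity $\mu(\mathrm{rev}\,d) = -\mu(d) - 2/L$ — both are
exploited as test oracles. With zero total coverage mu is *undefined*,
represented as `NA` and handled as a first-class state throughout: such
transcripts are excluded from window fitting, reported separately, and can
never pass the filter.

Well-covered transcripts concentrate near 0; degenerate ones collapse toward
$\pm 1$ depending on which end the pile-up hits. A population of degenerate
transcripts is therefore *bimodal* in mu.

## Detecting the onset of bimodality

Transcripts are ranked by length-normalized expression (raw count per
kilobase of the representative transcript; used only for ordering, never for
inference). Windows of 250 consecutive ranked transcripts, advanced 10 ranks
at a time, are histogrammed over $[-1, 1]$ and fitted to the double-beta
mixture

$$H\left[\frac{(1+x)\bigl(1-\tfrac12(1+x)\bigr)^{1+b}}{2B(2,2+b)} +
\frac{(1+x)^{1+a}\bigl(1-\tfrac12(1+x)\bigr)}{2^{1+a}B(2+a,2)}\right]$$

with $a, b \ge 0$. In $u = (1+x)/2$ the two terms are mirrored
$\mathrm{Beta}(2, 2+b)$ and $\mathrm{Beta}(2+a, 2)$ densities: $a = b = 0$
is a single symmetric hump, and growing $a$ (or $b$) pushes one component's
mass toward $+1$ (or $-1$). Scanning from the highest expression downward,
the first window whose fit exceeds 2 in either parameter marks the cutoff;
transcripts whose expression is *strictly greater* than that window's
lowest-expressed member pass the filter. Because the ranking is total and
the boundary is an expression value, the passing set is always a prefix of
the ranking. If no window ever triggers, everything ranked passes and a
warning says so.

## Numerical choices

These are implementation decisions the procedure itself leaves open; each is
configurable via `clear_config()`.

* **Histogram bins.** 25 equal-width bins on $[-1,1]$ (width 0.08), giving
  about 10 expected counts per bin at window size 250 — enough resolution to
  separate a central hump from shoulders at $\pm 0.7$ without starving bins.
  The first bin's lower edge is closed so the exact value $-1$ is counted.
* **Normalization `H`.** Each mixture component integrates to 2 over
  $[-1,1]$, so the bracket integrates to 4 and fixing
  $H = N\,\Delta x / 4$ makes expected counts sum to the window size $N$.
  This is the default; `fit_H = TRUE` lets `H` float (bounded positive) as a
  robustness option, and the tests confirm shape parameters are recovered
  either way.
* **The fit.** Box-constrained Levenberg–Marquardt least squares on the raw
  bin counts, $a, b \in [0, 100]$ (the upper bound keeps the optimizer
  finite; a fully collapsed window fits near it, far above the trigger).
  A 3×3 multi-start grid over $\{0.1, 1, 5\}^2$ guards against local minima;
  the start with the smallest residual sum of squares wins. Refitting the
  model's own expected counts over $(a,b) \in \{0, 0.5, 1, 2, 5\}^2$
  recovers every grid point to ~1e-13.
* **Failed fits** (no start converges) skip the window with a logged
  warning. A numerical failure must not silently discard data, and must not
  trigger the cutoff either.
* **Boundary ties** share the boundary expression value and are excluded —
  "higher than" is read strictly, the conservative direction.
* **Expression source.** A counts table takes precedence; without one,
  mean coverage per base ($\sum d_k / L$) is used and the run manifest
  records which. Under coverage-derived expression the whole pipeline is
  scale-invariant: multiplying all depths by a constant changes no mu, no
  rank, no cutoff.
* **Gene–transcript joining** is by gene identifier string equality
  (`gene_map` for BED12, the gene-symbol column for refFlat/extended
  genePred). Entries on one side only are dropped and counted in a
  reconciliation log rather than guessed at.

## What the simulator emulates — and what it does not

`simulate_clear_data()` generates the regimes the detector assumes, on a
synthetic chromosome with real exon/intron structure so the whole genomic
code path (BedGraph parsing, projection, intron exclusion, strand reversal)
is exercised:

* per-kb expression is log-normal (meanlog $\log 25$, sdlog 2 — a wide
  dynamic range typical of mammalian libraries);
* transcripts above the onset rank (default 2,000 of 7,000) place reads
  uniformly; below it each transcript is skewed toward one end (equal
  mixture of Beta(5,1) and Beta(1,5) positional laws, giving mu clusters
  near $\pm 2/3$) or drops out entirely (rate 0.2);
* each read contributes +1 depth over a 100 nt span centered on its drawn
  position, clipped at transcript ends, at 0.4 expected reads per
  (per-kb expression unit × kb) — a few hundred thousand reads per sample,
  the scale of a shallow limiting-cell library;
* everything derives from one mandatory seed; identical spec and seed give
  byte-identical files.

Validation runs use 7,000 genes and 20 seeds for cutoff recovery (the
detected cutoff rank must fall within one window span of the planted onset,
with no trigger above it), and smaller gene counts (120–800) for round-trip,
determinism and property tests.

The simulator deliberately does **not** model alignment error, isoform
mixtures, GC or fragmentation bias, read-level FASTQ data, or any
PCR-duplicate mechanism beyond positional pile-ups. Passing tests therefore
demonstrate that the statistics and the cutoff scan behave as designed under
the model's own assumptions — they do not certify behaviour on real
libraries, where the bias onset is gradual and mixed with technical
structure the model omits. The QC plots (`plot_mu()`) exist precisely so an
analyst can confirm the characteristic bifurcation on real data before
trusting the cutoff.

## Degenerate inputs

Empty coverage gives all-undefined mu, zero passes, and a warning — not an
error. Fewer ranked transcripts than one window: no fit is attempted,
everything passes, with a warning. Chromosomes present in the annotation but
absent from the track project to zeros and are counted in a warning (a
chromosome-naming mismatch is visible, not silent); an alias map argument
handles `chr1`-versus-`1` conventions. Overlapping BedGraph intervals,
negative depths and malformed records are hard errors naming the line.

## Cross-sample selection and the fold-change bound

`intersect_clear()` keeps transcripts passing in at least `min_samples`
samples (default: all, the strict intersection; monotone in
`min_samples` by construction). For a gene passing in one group and failing
in another, no fold change is quantifiable — but substituting the failing
sample's cutoff expression for its unreliable count gives
`fold_change_bound() = log2(mean_high / cutoff)`, a conservative bound:
any true value below the cutoff would only make the ratio larger. The
pass/fail matrix distinguishes "excluded" (ranked, below cutoff) from
"undefined" (no usable mu) to aid QC triage; no automated
pass-here/fail-there DEG call is made, since no principled replicate
threshold exists for it.

## Known limitations

* One representative transcript per gene: isoform-specific coverage is
  averaged into whatever the longest transcript's coordinates make of it.
* The double-beta family cannot represent a *tighter-than-Beta(2,2)* central
  spike, so very uniform windows fit at the $a = b = 0$ boundary; this is
  harmless for cutoff detection but the fitted values are not a calibrated
  spread measure.
* The cutoff is a single expression threshold; a gradual degradation regime
  is reduced to the first window that crosses the trigger.
* Multi-mapped and duplicate-read handling happens upstream of the BedGraph
  input and is invisible here.
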