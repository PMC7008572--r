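Package: clearseq
Title: Coverage-Based Prefiltering of Limiting-Cell RNA-Seq (CLEAR)
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies reliably quantifiable transcripts in low-input
    (limiting-cell) RNA-seq libraries before differential-expression
    analysis.  For every gene's longest transcript the positional mean of
    per-base exonic read coverage is mapped to a skew statistic mu in
    [-1, 1] (-1 = all signal at the 5' end, +1 = all at the 3' end).
    Transcripts are ranked by length-normalized expression, sliding
    windows of mu values are fitted to a double-beta mixture, and the
    expression level where the mu distribution first turns bimodal
    (either shape parameter exceeding 2) defines the CLEAR cutoff.
    Transcripts above the cutoff in all (or a chosen subset of) samples
    form an analysis-ready whitelist.  Includes BedGraph/BED12/genePred
    readers, a synthetic-data generator for validation, QC plots, and a
    conservative fold-change bound for genes failing the filter in one
    group.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    grDevices,
    IRanges,
    jsonlite,
    minpack.lm,
    methods,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
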