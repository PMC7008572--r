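# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", ".I", ".N", ".SD", "gene_id", "transcript_id", "length_L",
  "n_zero_exons", "norm_expression", "raw_count", "chrom", "start", "end",
  "depth", "orig", "mu", "total", "coverage_per_base", "rank",
  "window_index", "pass", "n_pass", "best_rank", "status", "sample_id",
  "gene_idx", "n_reads", "rank_true", "regime", "abundance", "V1"))
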