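# Stage 3: per-sample peak scores -> score-per-million -> pooled
# iterative overlap removal -> consensus matrix -> support/SPM/autosome
# filters. The consensus SPM matrix feeds caQTL mapping.

source("analysis/00_config.R")

peaks <- read_peak_bed(res_path("peaks_truth.bed"))
vals <- read_matrix_tsv(res_path("accessibility_truth.tsv"))
acc <- structure(list(peaks = peaks[match(rownames(vals), peaks$name), ],
  values = vals), class = "accessibility_matrix")

calls <- simulate_peak_calls(acc)
calls <- lapply(calls, function(p) {
  p$score <- spm_normalize(p$score)
  p
})
consensus <- build_consensus(calls)
filtered <- filter_consensus(consensus, min_samples = 2, min_spm = 5)

write.table(
  data.frame(filtered$peaks, n_samples_observed = filtered$n_samples_observed),
  res_path("consensus_peaks.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
write_matrix_tsv(filtered$values, res_path("consensus_spm.tsv"), "peak")

cat(sprintf("pooled %d per-sample calls -> %d consensus peaks -> %d after filters\n",
  sum(vapply(calls, nrow, 0L)), nrow(consensus$peaks), nrow(filtered$peaks)))
cat(sprintf("all consensus peaks width 501: %s\n",
  all(filtered$peaks$end - filtered$peaks$start == 501)))
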