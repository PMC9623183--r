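# Stage 4: map consensus peaks to merged chromatin states (promoter /
# transcribed / enhancer / polycomb / ZNF-repeats / heterochromatin /
# quiescent), and test enrichment against width-matched shuffled
# backgrounds.

source("analysis/00_config.R")

peaks <- read.delim(res_path("consensus_peaks.tsv"))
track <- state_track(read_interval_bed(res_path("states.bed")))

labels <- assign_state(peaks, track)
cfg <- cohort_config()
bg <- shuffle_background(peaks[, c("chrom", "start", "end")],
  setNames(cfg$chrom_length, cfg$chrom), seed = COHORT_SEED + 100L)
enrichment <- state_enrichment(peaks, bg, track)

write.table(data.frame(peak = peaks$name, state = labels),
  res_path("peak_states.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
write.table(enrichment, res_path("state_enrichment.tsv"), sep = "\t",
  quote = FALSE, row.names = FALSE)

cat("peak state composition:\n")
print(table(labels))
top <- enrichment[order(enrichment$p_value), ][1, ]
cat(sprintf("strongest enrichment: %s (OR %.2f [%.2f, %.2f], p = %.3g)\n",
  top$category, top$odds_ratio, top$ci_low, top$ci_high, top$p_value))
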