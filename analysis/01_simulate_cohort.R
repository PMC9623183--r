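# Stage 1: draw the synthetic cohort — genotypes in HWE with LD blocks,
# accessibility with planted caQTL effects, expression with a mediation
# chain, survival with a genotype-dependent hazard, and a chromatin-state
# track — and write every input table under results/.

source("analysis/00_config.R")

cfg <- cohort_config()
geno <- simulate_genotypes(cfg)
acc <- simulate_accessibility(geno, cfg)
expr <- simulate_expression(geno, acc, cfg)
surv <- simulate_survival(geno, cfg)
states <- simulate_state_track(cfg)
clinical <- local({
  set.seed(cfg$seed + 5L)
  data.frame(donor = geno$samples,
    age = round(rnorm(cfg$n_samples, 60, 10), 1),
    sex = sample(c(0L, 1L), cfg$n_samples, replace = TRUE),
    stage = sample(1:3, cfg$n_samples, replace = TRUE))
})

write_genotype_tsv(geno, res_path("genotypes.tsv"))
write_peak_bed(acc$peaks, res_path("peaks_truth.bed"))
write_matrix_tsv(acc$values, res_path("accessibility_truth.tsv"), "peak")
write_matrix_tsv(expr$values, res_path("expression.tsv"), "gene")
write.table(expr$tss, res_path("gene_tss.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
write_survival_tsv(surv, res_path("survival.tsv"))
write.table(states$intervals[, c("chrom", "start", "end", "label")],
  res_path("states.bed"), sep = "\t", quote = FALSE, row.names = FALSE,
  col.names = FALSE)
write.table(clinical, res_path("clinical.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

cat(sprintf(
  "cohort: %d donors, %d variants, %d peaks, %d genes; %.0f%% censoring\n",
  cfg$n_samples, cfg$n_variants, cfg$n_peaks, nrow(expr$values),
  100 * mean(surv$event == 0)))
cat("planted: 2 caQTLs, 1 mediated gene (TE = 2), 1 survival variant (HR 2)\n")
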