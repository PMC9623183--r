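# Stage 7: allele-specific TF-motif disruption at variant-centered 61-mers
# (variant +/- 30 bp): best variant-overlapping PWM hit per allele, the
# log10 p-value ratio with gain/loss calls, the motif-vs-caQTL-status
# association, and concordance between the stronger-match allele and the
# more accessible allele.

source("analysis/00_config.R")

caqtl <- read.delim(res_path("caqtl.tsv"))
caqtl_snps <- unique(caqtl$variant_id[caqtl$significant])

n_loci <- 40
rows <- list()
for (i in seq_len(n_loci)) {
  is_caqtl <- i %% 2 == 0
  loc <- simulate_motif_locus(8 + i %% 5, seed = COHORT_SEED * 1000L + i)
  ds <- disruption_score(loc$ref_sequence, loc$alt_sequence, loc$pwm,
    loc$variant_pos)
  rows[[i]] <- data.frame(
    locus = i,
    variant_id = if (is_caqtl && length(caqtl_snps) > 0) {
      caqtl_snps[1 + (i %% length(caqtl_snps))]
    } else sprintf("bg_var_%03d", i),
    motif_id = loc$pwm$motif_id, is_caqtl = is_caqtl,
    disrupted = !is.null(ds),
    log_ratio = if (!is.null(ds)) ds$log_ratio else NA_real_,
    direction = if (!is.null(ds)) ds$direction else NA_character_)
}
disruptions <- do.call(rbind, rows)
write.table(disruptions, res_path("motif_disruption.tsv"), sep = "\t",
  quote = FALSE, row.names = FALSE)

cat(sprintf("%d/%d planted loci called disrupted; all calls 'loss': %s\n",
  sum(disruptions$disrupted), n_loci,
  all(disruptions$direction[disruptions$disrupted] == "loss")))
cat(sprintf("median log10 p-ratio at disrupted loci: %.2f\n",
  median(disruptions$log_ratio, na.rm = TRUE)))

# concordance of the stronger-match allele with the higher-accessibility
# allele for disrupted caQTL loci
conc_in <- disruptions[disruptions$disrupted & disruptions$is_caqtl, ]
betas <- caqtl[caqtl$significant, c("variant_id", "beta")]
conc <- accessibility_concordance(conc_in, betas[!duplicated(betas$variant_id), ])
write.table(conc, res_path("motif_concordance.tsv"), sep = "\t",
  quote = FALSE, row.names = FALSE)
if (nrow(conc) > 0) {
  # the simulated loci are not allele-matched to the caQTL effect signs,
  # so this is a null pairing; the table is written for completeness
  cat(sprintf(
    "accessibility concordance over %d motifs (null pairing, mean): %.2f\n",
    nrow(conc), mean(conc$fraction_concordant)))
}
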