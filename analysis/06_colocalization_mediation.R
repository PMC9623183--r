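# Stage 6: pair caQTL peaks with eQTL genes through the lead SNP and its
# LD, compute the shared-causal posterior (PP4 > 0.8 = colocalized), and
# quantify mediation of the expression effect through accessibility with
# a 1,000-resample bootstrap in both causal directions.

source("analysis/00_config.R")

caqtl <- read.delim(res_path("caqtl.tsv"))
eqtl <- read.delim(res_path("eqtl.tsv"))
geno <- read_genotype_tsv(res_path("genotypes_qc.tsv"))
spm <- read_matrix_tsv(res_path("consensus_spm.tsv"))
expr <- read_matrix_tsv(res_path("expression.tsv"))

pairs <- select_coloc_pairs(caqtl, eqtl, geno)
coloc <- colocalize_pairs(pairs, caqtl, eqtl)
write.table(coloc, res_path("coloc.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
cat(sprintf("coloc: %d candidate pair(s), %d colocalized (PP4 > 0.8)\n",
  nrow(coloc), sum(coloc$colocalized)))
if (nrow(coloc) > 0) print(coloc)

rows <- list()
for (r in which(coloc$colocalized)) {
  dos <- geno$dosages[, coloc$lead_snp[r]]
  donors <- intersect(names(dos), colnames(spm))
  both <- mediate_both_directions(dos[donors],
    spm[coloc$peak_id[r], donors], expr[coloc$gene_id[r], donors],
    n_boot = 1000, seed = COHORT_SEED + r)
  for (dir in c("forward", "reverse")) {
    m <- both[[dir]]
    rows[[length(rows) + 1]] <- data.frame(
      peak_id = coloc$peak_id[r], gene_id = coloc$gene_id[r],
      variant_id = coloc$lead_snp[r], direction = dir,
      acme = m$acme$estimate, acme_ci_low = m$acme$ci_low,
      acme_ci_high = m$acme$ci_high, acme_p = m$acme$p_value,
      ade = m$ade$estimate, ade_p = m$ade$p_value,
      te = m$te$estimate, te_p = m$te$p_value,
      prop_mediated = m$prop_mediated)
  }
}
mediation <- if (length(rows)) do.call(rbind, rows) else
  data.frame(peak_id = character(0))
write.table(mediation, res_path("mediation.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
if (nrow(mediation) > 0) {
  fwd <- mediation[mediation$direction == "forward", ]
  cat(sprintf(
    "mediation (forward): ACME %.3g (p = %.3g), ADE %.3g (p = %.3g), %.0f%% mediated\n",
    fwd$acme[1], fwd$acme_p[1], fwd$ade[1], fwd$ade_p[1],
    100 * fwd$prop_mediated[1]))
}
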