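# Stage 2: variant QC (INFO >= 0.4, MAF >= 5%, missing < 5%, exact HWE
# p > 1e-6) and genotype principal components for population structure.

source("analysis/00_config.R")

geno <- read_genotype_tsv(res_path("genotypes.tsv"))
qc <- filter_variants(geno)
pcs <- genotype_pca(qc$genotypes, n_components = 5)

write.table(qc$report, res_path("qc_report.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
write_genotype_tsv(qc$genotypes, res_path("genotypes_qc.tsv"))
write.table(data.frame(donor = rownames(pcs), pcs),
  res_path("genotype_pcs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

counts <- attr(qc$report, "counts")
cat(sprintf("QC: %d/%d variants retained (removed: %d MAF, %d missing, %d HWE, %d INFO)\n",
  counts["retained"], counts["input"], counts["removed_maf"],
  counts["removed_missing"], counts["removed_hwe"], counts["removed_info"]))
cat(sprintf("PC1 variance share of top-5: %.2f\n",
  var(pcs[, 1]) / sum(apply(pcs, 2, var))))
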