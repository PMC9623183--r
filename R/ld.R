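## Linkage disequilibrium from genotype dosages (composite r-squared) and
## GWAS-locus overlap via LD regions around catalog tag SNPs.

#' Pairwise LD as squared dosage correlation
#'
#' Squared Pearson correlation of the two dosage vectors over jointly
#' non-missing samples (the composite / Rogers-Huff convention, which at
#' HWE closely tracks haplotype r-squared). Returns NA with a `reason`
#' attribute when fewer than 3 complete pairs remain or either variant is
#' monomorphic in the complete subset.
#'
#' @param dosage_a,dosage_b dosage vectors (0/1/2/NA), same length.
#' @return r-squared in [0, 1], or NA with attr "reason".
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[ok]
  b <- dosage_b[ok]
  undefined <- function(reason) structure(NA_real_, reason = reason)
  if (length(a) < 3) return(undefined("fewer than 3 jointly non-missing samples"))
  if (sd(a) == 0 || sd(b) == 0) return(undefined("monomorphic in complete subset"))
  cor(a, b)^2
}

#' LD region around a tag variant
#'
#' All variants within `window` bp of the tag whose r-squared with the
#' tag strictly exceeds `threshold`, plus the tag itself (r2 = 1).
#'
#' @param tag variant id present in `genotypes`.
#' @param genotypes a [genotype_matrix()].
#' @param window search window in bp (default 1e6).
#' @param threshold r-squared cutoff, strict (default 0.5).
#' @return data.frame variant_id, r2 with attr "tag" and "threshold".
#' @export
ld_region <- function(tag, genotypes, window = 1e6, threshold = 0.5) {
  vi <- match(tag, genotypes$variants$id)
  if (is.na(vi)) abort("tag variant %s not in genotypes", tag)
  v <- genotypes$variants
  near <- which(v$chrom == v$chrom[vi] & abs(v$pos - v$pos[vi]) <= window &
    v$id != tag)
  r2 <- vapply(near, function(j) {
    as.numeric(ld_r2(genotypes$dosages[, vi], genotypes$dosages[, j]))
  }, 0.0)
  keep <- !is.na(r2) & r2 > threshold
  out <- data.frame(
    variant_id = c(tag, v$id[near][keep]),
    r2 = c(1.0, r2[keep]),
    stringsAsFactors = FALSE
  )
  attr(out, "tag") <- tag
  attr(out, "threshold") <- threshold
  out
}

#' GWAS-related caQTLs via LD-region overlap
#'
#' For each GWAS catalog variant present in the genotypes (non-biallelic
#' entries are expected to be removed upstream), builds its LD region and
#' reports every caQTL SNP that falls inside it.
#'
#' @param caqtl_results output of [map_caqtls()] (significant records are
#'   used; pass a pre-filtered table to change that).
#' @param gwas_variants data.frame variant_id, chrom, pos, trait.
#' @param genotypes a [genotype_matrix()].
#' @param threshold LD r-squared cutoff, strict (default 0.5).
#' @param window LD search window in bp.
#' @return data.frame caqtl_snp, gwas_snp, r2, trait, is_direct_overlap.
#' @export
gwas_overlap <- function(caqtl_results, gwas_variants, genotypes,
                         threshold = 0.5, window = 1e6) {
  caqtl_snps <- unique(caqtl_results$variant_id[
    if ("significant" %in% names(caqtl_results)) caqtl_results$significant
    else rep(TRUE, nrow(caqtl_results))])
  gwas <- gwas_variants[gwas_variants$variant_id %in% genotypes$variants$id, ,
    drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(gwas))) {
    region <- ld_region(gwas$variant_id[r], genotypes,
      window = window, threshold = threshold)
    hit <- intersect(caqtl_snps, region$variant_id)
    if (length(hit) == 0) next
    out[[length(out) + 1]] <- data.frame(
      caqtl_snp = hit, gwas_snp = gwas$variant_id[r],
      r2 = region$r2[match(hit, region$variant_id)],
      trait = gwas$trait[r],
      is_direct_overlap = hit == gwas$variant_id[r],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(caqtl_snp = character(0), gwas_snp = character(0),
      r2 = numeric(0), trait = character(0),
      is_direct_overlap = logical(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
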