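## Variant-level genotype quality control: MAF, missingness, exact
## Hardy-Weinberg test, combined filtering, and PCA covariates for
## population structure.

#' Construct a genotype matrix object
#'
#' Dosages are alt-allele counts in \{0, 1, 2\} with NA for missing, stored
#' samples x variants. Variant metadata carries id, chrom, 1-based pos, the
#' two alleles and an optional imputation INFO score.
#'
#' @param dosages samples x variants numeric matrix of 0/1/2/NA.
#' @param variants data.frame with columns id, chrom, pos, ref, alt and
#'   optionally info_score.
#' @param samples ordered sample ids (default from matrix rownames).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, samples = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(samples)) abort("sample ids required (rownames or `samples`)")
  if (!all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants))) {
    abort("variants needs columns id, chrom, pos, ref, alt")
  }
  if (!"info_score" %in% names(variants)) variants$info_score <- NA_real_
  if (nrow(variants) != ncol(dosages)) {
    abort("variant table (%d rows) does not match dosage columns (%d)",
      nrow(variants), ncol(dosages))
  }
  if (anyDuplicated(variants$id)) abort("variant ids must be unique")
  if (anyDuplicated(samples)) abort("sample ids must be unique")
  if (any(variants$pos < 1)) abort("positions must be >= 1 (1-based)")
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) abort("dosages must be 0, 1, 2 or NA")
  rownames(dosages) <- samples
  colnames(dosages) <- variants$id
  structure(
    list(dosages = dosages, variants = variants, samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
    length(x$samples), nrow(x$variants)))
  invisible(x)
}

#' Minor allele frequency of a dosage vector
#'
#' Missing entries are excluded; the returned frequency is
#' min(f_alt, 1 - f_alt), so always in [0, 0.5].
#'
#' @param dosage_vector numeric vector of 0/1/2/NA alt-allele counts.
#' @return minor allele frequency.
#' @export
compute_maf <- function(dosage_vector) {
  x <- dosage_vector[!is.na(dosage_vector)]
  if (length(x) == 0) abort("all dosages missing: MAF undefined")
  f_alt <- sum(x) / (2 * length(x))
  min(f_alt, 1 - f_alt)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, the p-value is
#' the total probability of all heterozygote configurations whose
#' conditional probability does not exceed that of the observed
#' configuration. Probabilities follow the standard hypergeometric-type
#' distribution of heterozygote counts given allele totals.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) abort("genotype counts must be nonnegative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) abort("no genotyped samples: HWE test undefined")
  ## work with the rarer allele
  n_a <- 2 * n_aa + n_Aa
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_a, n_A)
  het_obs <- n_Aa
  ## possible heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- hwe_het_logprob(hets, rare, n)
  logp <- logp - logsumexp(logp)
  p_obs <- logp[match(het_obs, hets)]
  if (is.na(p_obs)) abort("inconsistent genotype counts")
  ## sum configurations no more probable than observed (tolerance guards
  ## against log-scale ties being split by rounding)
  min(1, sum(exp(logp[logp <= p_obs + 1e-12])))
}

## log unnormalized probability of `het` heterozygotes given `rare` rare
## alleles among n diploids
hwe_het_logprob <- function(het, rare, n) {
  hom_rare <- (rare - het) / 2
  hom_com <- n - het - hom_rare
  lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(het + 1) - lgamma(hom_com + 1) +
    het * log(2)
}

#' Filter variants on INFO, MAF, missing rate and HWE
#'
#' Retains variants with INFO >= `min_info` (skipped with a message when no
#' variant carries an INFO score), MAF >= `min_maf`, missing rate strictly
#' below `max_missing`, and exact HWE p strictly above `min_hwe_p`. The
#' report attributes each removal to the first failing criterion in that
#' order.
#'
#' @param geno a [genotype_matrix()].
#' @param min_info minimum imputation INFO score (inclusive).
#' @param min_maf minimum minor allele frequency (inclusive).
#' @param max_missing maximum missing rate (exclusive).
#' @param min_hwe_p minimum HWE exact p-value (exclusive).
#' @return list with `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (per-variant QC metrics, pass flags and removal attribution).
#' @export
filter_variants <- function(geno, min_info = 0.4, min_maf = 0.05,
                            max_missing = 0.05, min_hwe_p = 1e-6) {
  stopifnot(inherits(geno, "genotype_matrix"))
  dos <- geno$dosages
  n_var <- ncol(dos)
  maf <- apply(dos, 2, function(v) {
    if (all(is.na(v))) NA_real_ else compute_maf(v)
  })
  missing_rate <- colMeans(is.na(dos))
  hwe_p <- apply(dos, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    hwe_exact_test(sum(v == 0), sum(v == 1), sum(v == 2))
  })
  info <- geno$variants$info_score
  info_available <- any(!is.na(info))
  if (!info_available) {
    message("no INFO scores present; INFO criterion skipped")
  }
  pass_info <- if (info_available) !is.na(info) & info >= min_info else rep(TRUE, n_var)
  pass_maf <- !is.na(maf) & maf >= min_maf
  pass_missing <- missing_rate < max_missing
  pass_hwe <- !is.na(hwe_p) & hwe_p > min_hwe_p
  keep <- pass_info & pass_maf & pass_missing & pass_hwe
  removed_by <- rep(NA_character_, n_var)
  removed_by[!pass_hwe] <- "hwe"
  removed_by[!pass_missing] <- "missing_rate"
  removed_by[!pass_maf] <- "maf"
  removed_by[!pass_info] <- "info"
  report <- data.frame(
    id = geno$variants$id, maf = maf, missing_rate = missing_rate,
    hwe_p = hwe_p, info_score = info,
    pass_info = pass_info, pass_maf = pass_maf,
    pass_missing = pass_missing, pass_hwe = pass_hwe,
    retained = keep, removed_by = removed_by,
    stringsAsFactors = FALSE
  )
  counts <- c(
    input = n_var, retained = sum(keep),
    removed_info = sum(removed_by == "info", na.rm = TRUE),
    removed_maf = sum(removed_by == "maf", na.rm = TRUE),
    removed_missing = sum(removed_by == "missing_rate", na.rm = TRUE),
    removed_hwe = sum(removed_by == "hwe", na.rm = TRUE)
  )
  attr(report, "counts") <- counts
  filtered <- genotype_matrix(
    dos[, keep, drop = FALSE],
    geno$variants[keep, , drop = FALSE],
    geno$samples
  )
  list(genotypes = filtered, report = report)
}

#' Genotype principal components
#'
#' Missing dosages are mean-imputed per variant, the matrix is centered
#' (not scaled) and PCs are extracted. Sign convention: within each
#' component the loading of largest magnitude is positive.
#'
#' @param geno a [genotype_matrix()].
#' @param n_components number of PCs (default 5, the usual covariate count
#'   for population structure).
#' @return samples x components score matrix (columns PC1..PCk).
#' @export
genotype_pca <- function(geno, n_components = 5) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n <- length(geno$samples)
  if (n < n_components) {
    abort("need at least %d samples for %d components, have %d",
      n_components, n_components, n)
  }
  x <- geno$dosages
  for (j in seq_len(ncol(x))) {
    mj <- is.na(x[, j])
    if (any(mj)) x[mj, j] <- mean(x[, j], na.rm = TRUE)
  }
  xc <- scale(x, center = TRUE, scale = FALSE)
  ## constant variants carry no information
  keep <- apply(xc, 2, function(v) any(v != 0))
  if (!any(keep)) {
    scores <- matrix(0, n, n_components,
      dimnames = list(geno$samples, paste0("PC", seq_len(n_components))))
    return(scores)
  }
  pc <- prcomp(xc[, keep, drop = FALSE], center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  if (k < n_components) {
    scores <- cbind(scores, matrix(0, n, n_components - k))
  }
  dimnames(scores) <- list(geno$samples, paste0("PC", seq_len(n_components)))
  scores
}
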