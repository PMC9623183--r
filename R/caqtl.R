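## Cis-caQTL mapping: hidden-factor covariates from the accessibility
## matrix, candidate (variant, peak) pairs inside the cis window, per-pair
## OLS, and genome-wide Benjamini-Hochberg FDR.

#' Hidden accessibility factors (PEER-count PCA surrogate)
#'
#' Extracts the top principal components of the centered, unit-scaled
#' peak x sample matrix as hidden confounder covariates. The default
#' factor count follows the 25%-of-sample-size rule (rounded half-up).
#' Sign convention matches [genotype_pca()].
#'
#' @param acc an `accessibility_matrix`.
#' @param k number of factors; default `round(0.25 * n_samples)`.
#' @return samples x k factor score matrix (k = 0 gives a 0-column
#'   matrix and the pipeline proceeds without hidden factors).
#' @export
hidden_factors <- function(acc, k = NULL) {
  x <- t(acc$values) # samples x peaks
  n <- nrow(x)
  if (n < 4) abort("need at least 4 samples for hidden factors")
  if (is.null(k)) k <- floor(0.25 * n + 0.5)
  if (k == 0) {
    return(matrix(0, n, 0, dimnames = list(rownames(x), NULL)))
  }
  if (k >= n) abort("k = %d factors requires more than %d samples", k, n)
  keep <- apply(x, 2, function(v) sd(v) > 0)
  x <- scale(x[, keep, drop = FALSE])
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("factor_", seq_len(k))
  scores
}

#' Candidate cis (variant, peak) pairs
#'
#' A pair is tested when variant and peak share a chromosome and the
#' distance between the SNP and the nearest peak edge is at most `window`
#' (inclusive); a SNP inside the peak has distance 0. The signed distance
#' is negative when the SNP lies upstream of the peak start.
#'
#' @param variants variant data.frame (id, chrom, pos 1-based).
#' @param peaks peak data.frame.
#' @param window cis window in bp (default 1e6).
#' @return data.frame variant_id, peak_id, distance_bp (signed).
#' @export
cis_pairs <- function(variants, peaks, window = 1e6) {
  out <- list()
  for (ch in intersect(unique(variants$chrom), unique(peaks$chrom))) {
    v <- variants[variants$chrom == ch, , drop = FALSE]
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (nrow(v) == 0 || nrow(p) == 0) next
    snp0 <- v$pos - 1L # 0-based
    ## signed distance matrix: rows variants, cols peaks
    d_start <- outer(snp0, p$start, `-`)       # >=0 when snp at/after start
    d_end <- outer(snp0, p$end - 1L, `-`)      # <=0 when snp at/before last base
    dist <- ifelse(d_start >= 0 & d_end <= 0, 0L,
      ifelse(d_start < 0, d_start, d_end))
    hit <- which(abs(dist) <= window, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    out[[ch]] <- data.frame(
      variant_id = v$id[hit[, 1]], peak_id = p$name[hit[, 2]],
      distance_bp = dist[hit], stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(variant_id = character(0), peak_id = character(0),
      distance_bp = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Single-pair linear QTL fit
#'
#' OLS of the phenotype on dosage, an intercept and covariates; samples
#' with missing dosage are dropped pairwise. Returns the dosage slope,
#' its standard error, the t statistic (residual df) and the two-sided p.
#'
#' @param dosage numeric dosage vector (0/1/2/NA).
#' @param phenotype_vector aligned phenotype values.
#' @param covariates optional samples x covariates matrix.
#' @return list(beta, se, t, p, df, n).
#' @export
fit_linear_qtl <- function(dosage, phenotype_vector, covariates = NULL) {
  ok <- !is.na(dosage) & !is.na(phenotype_vector)
  if (!is.null(covariates)) ok <- ok & complete.cases(covariates)
  d <- dosage[ok]
  y <- phenotype_vector[ok]
  X <- cbind(intercept = 1, dosage = d)
  if (!is.null(covariates)) {
    X <- cbind(X, as.matrix(covariates)[ok, , drop = FALSE])
  }
  n <- length(y)
  if (n < ncol(X) + 1) abort("too few samples (%d) for %d coefficients", n, ncol(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort("rank-deficient design; collinear column(s): %s",
      paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, y)
  res <- y - X %*% coefs
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  beta <- coefs[["dosage"]]
  t_stat <- if (se > 0) beta / se else sign(beta) * Inf
  p <- 2 * pt(-abs(t_stat), df)
  list(beta = beta, se = se, t = t_stat, p = p, df = df, n = n)
}

#' Map cis-caQTLs
#'
#' Fits every cis pair with the shared covariates and applies
#' Benjamini-Hochberg FDR jointly over all tested pairs; a record is
#' significant when fdr < `fdr_threshold` (strict). Samples are aligned
#' by id intersection across genotypes, phenotype and covariates. When no
#' dosage is missing, per-pair fits use a residualization fast path that
#' is algebraically identical to the full OLS.
#'
#' @param genotypes a [genotype_matrix()].
#' @param acc an `accessibility_matrix` (or any list with `peaks` and
#'   `values` in the same shape — expression mapping reuses this with
#'   gene TSS standing in for peaks).
#' @param covariates samples x covariates matrix (rownames = sample ids)
#'   or NULL.
#' @param window cis window in bp.
#' @param fdr_threshold significance threshold on BH FDR.
#' @return data.frame of QTL association records.
#' @export
map_caqtls <- function(genotypes, acc, covariates = NULL, window = 1e6,
                       fdr_threshold = 0.05) {
  samples <- intersect(genotypes$samples, colnames(acc$values))
  if (!is.null(covariates)) samples <- intersect(samples, rownames(covariates))
  if (length(samples) == 0) abort("no overlapping samples across inputs")
  dos <- genotypes$dosages[samples, , drop = FALSE]
  phen <- acc$values[, samples, drop = FALSE]
  covs <- if (!is.null(covariates)) {
    as.matrix(covariates)[samples, , drop = FALSE]
  } else NULL
  pairs <- cis_pairs(genotypes$variants, acc$peaks, window)
  if (nrow(pairs) == 0) {
    return(data.frame(variant_id = character(0), peak_id = character(0),
      distance_bp = integer(0), beta = numeric(0), se = numeric(0),
      t = numeric(0), p = numeric(0), fdr = numeric(0),
      significant = logical(0)))
  }
  n <- length(samples)
  no_missing <- !anyNA(dos)
  if (no_missing) {
    ## residualize phenotype rows and dosage columns on [1 | covs] once
    C <- cbind(rep(1, n), covs)
    qc <- qr(C)
    rd <- dos - qr.fitted(qc, dos)
    ry <- t(phen) - qr.fitted(qc, t(phen)) # samples x peaks
    p_full <- ncol(C) + 1
    df <- n - p_full
    vi <- match(pairs$variant_id, colnames(dos))
    pi <- match(pairs$peak_id, rownames(phen))
    sdd <- colSums(rd^2)[vi]
    syy <- colSums(ry^2)[pi]
    sdy <- colSums(rd[, vi, drop = FALSE] * ry[, pi, drop = FALSE])
    beta <- sdy / sdd
    rss <- syy - beta^2 * sdd
    rss[rss < 0] <- 0
    se <- sqrt(rss / df / sdd)
    t_stat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
    p <- 2 * pt(-abs(t_stat), df)
  } else {
    fits <- mapply(function(v, pk) {
      f <- fit_linear_qtl(dos[, v], phen[pk, ], covs)
      c(f$beta, f$se, f$t, f$p, f$n)
    }, pairs$variant_id, pairs$peak_id)
    beta <- fits[1, ]; se <- fits[2, ]; t_stat <- fits[3, ]; p <- fits[4, ]
    n <- unname(fits[5, ])
  }
  fdr <- p.adjust(p, method = "BH")
  data.frame(
    variant_id = pairs$variant_id, peak_id = pairs$peak_id,
    distance_bp = pairs$distance_bp, beta = unname(beta), se = unname(se),
    t = unname(t_stat), p = unname(p), fdr = fdr,
    significant = fdr < fdr_threshold, n = n, stringsAsFactors = FALSE
  )
}

#' Lead variant per peak
#'
#' The lead association for each peak: smallest p, ties broken by smaller
#' |distance|, then lexical variant id — stable under row permutations.
#'
#' @param qtl_results output of [map_caqtls()].
#' @param significant_only restrict to significant records first.
#' @return one row per peak.
#' @export
lead_caqtls <- function(qtl_results, significant_only = FALSE) {
  df <- qtl_results
  if (significant_only) df <- df[df$significant, , drop = FALSE]
  if (nrow(df) == 0) return(df)
  ord <- order(df$peak_id, df$p, abs(df$distance_bp), df$variant_id)
  df <- df[ord, , drop = FALSE]
  out <- df[!duplicated(df$peak_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
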