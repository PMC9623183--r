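# Independent reference implementations (brute force / closed form) used
# as oracles against the package's optimized paths, plus small fixture
# builders. These deliberately avoid the package's own code paths.

# Exact HWE p-value by direct enumeration of heterozygote configurations,
# using factorial arithmetic on the conditional distribution given allele
# counts.
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  rare <- min(n_a, 2 * n - n_a)
  hets <- seq(rare %% 2, rare, by = 2)
  prob_het <- function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    choose(n, hom_r) * choose(n - hom_r, h) * 2^h
  }
  w <- vapply(hets, prob_het, 0.0)
  w <- w / sum(w)
  p_obs <- w[match(n_Aa, hets)]
  sum(w[w <= p_obs * (1 + 1e-12)])
}

# O(n^2) literal greedy iterative removal: keep top score, delete
# overlapping, repeat.
oracle_iterative_removal <- function(peaks) {
  remaining <- peaks
  kept <- peaks[0, ]
  while (nrow(remaining) > 0) {
    ord <- order(-remaining$score, remaining$chrom, remaining$start)
    top <- remaining[ord[1], ]
    kept <- rbind(kept, top)
    ov <- remaining$chrom == top$chrom &
      remaining$start < top$end & remaining$end > top$start
    remaining <- remaining[!ov, , drop = FALSE]
  }
  kept[order(kept$chrom, kept$start), ]
}

# Normal-equations OLS returning the dosage slope and its SE.
oracle_ols <- function(y, dosage, covariates = NULL) {
  X <- cbind(1, dosage)
  if (!is.null(covariates)) X <- cbind(X, covariates)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (length(y) - ncol(X))
  se <- sqrt(diag(xtx_inv) * sigma2)
  list(beta = unname(beta[2]), se = unname(se[2]))
}

# Exhaustive PWM match p-value: enumerate all 4^w words under the
# background and count those scoring at least `score`.
oracle_pwm_pvalue <- function(llr, background, score) {
  w <- ncol(llr)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(words))
  probs <- rep(1, nrow(words))
  for (j in seq_len(w)) {
    scores <- scores + llr[cbind(words[, j], j)]
    probs <- probs * background[words[, j]]
  }
  sum(probs[scores >= score - 1e-9])
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), span = 20000) {
  start <- sample.int(span, n, replace = TRUE)
  width <- sample(50:600, n, replace = TRUE)
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + width,
    name = sprintf("p%d", seq_len(n)),
    score = round(runif(n, 1, 100), 3),
    summit = start + width %/% 2L,
    stringsAsFactors = FALSE
  )
}

# small genotype matrix from an explicit dosage matrix
toy_genotypes <- function(dos, pos = NULL, chrom = "chr1") {
  m <- ncol(dos)
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = m)
  genotype_matrix(
    dos,
    data.frame(id = sprintf("v%d", seq_len(m)), chrom = chrom, pos = pos,
      ref = "A", alt = "G", stringsAsFactors = FALSE),
    samples = sprintf("s%d", seq_len(nrow(dos)))
  )
}
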