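sim_acc <- function(n = 40, peaks = 20, seed = 1, ...) {
  cfg <- sim_config(n_samples = n, n_variants = 30, n_peaks = peaks,
    seed = seed, ...)
  g <- simulate_genotypes(cfg)
  list(cfg = cfg, g = g, acc = simulate_accessibility(g, cfg))
}

test_that("hidden factor count follows the quarter-of-samples rule", {
  s <- sim_acc(n = 40, peaks = 30)
  hf <- hidden_factors(s$acc)
  expect_equal(ncol(hf), 10)
  expect_equal(nrow(hf), 40)
  hf0 <- hidden_factors(s$acc, k = 0)
  expect_equal(ncol(hf0), 0)
  expect_error(hidden_factors(s$acc, k = 40), "factors")
})

test_that("a planted batch shift loads on the first hidden factor", {
  s <- sim_acc(n = 60, peaks = 40, seed = 3)
  vals <- s$acc$values
  batch <- rep(c(0, 1), each = 30)
  vals <- vals + 5 * matrix(batch, nrow(vals), 60, byrow = TRUE)
  acc <- structure(list(peaks = s$acc$peaks, values = vals),
    class = "accessibility_matrix")
  hf <- hidden_factors(acc, k = 3)
  expect_gt(abs(cor(hf[, 1], batch)), 0.9)
})

test_that("cis pair enumeration matches brute force with inclusive 1 Mb bound", {
  variants <- data.frame(id = c("in_peak", "edge", "far", "other_chr"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(5100, 1005500, 2600000, 5100))
  peaks <- data.frame(chrom = "chr1", start = 5000, end = 5501,
    name = "pk1", score = 1, summit = 5250)
  pr <- cis_pairs(variants, peaks, window = 1e6)
  expect_setequal(pr$variant_id, c("in_peak", "edge"))
  expect_equal(pr$distance_bp[pr$variant_id == "in_peak"], 0)
  # edge: snp0 = 1005499, last peak base = 5500 -> exactly 999999... place at bound
  v2 <- data.frame(id = "exact", chrom = "chr1", pos = 1005501)
  expect_equal(nrow(cis_pairs(v2, peaks, window = 1e6)), 1) # exactly 1e6
  v3 <- data.frame(id = "past", chrom = "chr1", pos = 1005502)
  expect_equal(nrow(cis_pairs(v3, peaks, window = 1e6)), 0)
  # random layout vs brute force
  set.seed(12)
  vr <- data.frame(id = sprintf("v%d", 1:150), chrom = sample(c("chr1", "chr2"), 150, TRUE),
    pos = sample.int(3e6, 150))
  pk <- random_peaks(40, span = 3e6)
  got <- cis_pairs(vr, pk, window = 5e5)
  brute <- do.call(rbind, lapply(1:150, function(i) {
    do.call(rbind, lapply(1:40, function(j) {
      if (vr$chrom[i] != pk$chrom[j]) return(NULL)
      s0 <- vr$pos[i] - 1
      d <- if (s0 >= pk$start[j] && s0 < pk$end[j]) 0 else
        min(abs(s0 - pk$start[j]), abs(s0 - (pk$end[j] - 1)))
      if (d <= 5e5) data.frame(variant_id = vr$id[i], peak_id = pk$name[j]) else NULL
    }))
  }))
  expect_equal(nrow(got), nrow(brute))
  expect_setequal(paste(got$variant_id, got$peak_id),
    paste(brute$variant_id, brute$peak_id))
})

test_that("single-pair OLS matches the normal-equations oracle", {
  set.seed(8)
  for (i in 1:25) {
    n <- 60
    d <- rbinom(n, 2, 0.3)
    covs <- cbind(rnorm(n), rnorm(n))
    y <- 0.4 * d + covs %*% c(1, -0.5) + rnorm(n)
    fit <- fit_linear_qtl(d, y, covs)
    want <- oracle_ols(y, d, covs)
    expect_equal(fit$beta, want$beta, tolerance = 1e-8)
    expect_equal(fit$se, want$se, tolerance = 1e-8)
  }
  # noiseless: exact slope, extreme significance
  d <- rbinom(100, 2, 0.4)
  fit0 <- fit_linear_qtl(d, 2 * d)
  expect_equal(fit0$beta, 2, tolerance = 1e-12)
  expect_lt(fit0$p, 1e-100)
})

test_that("permuted dosages give uniform p-values", {
  set.seed(99)
  n <- 80
  y <- rnorm(n)
  d <- rbinom(n, 2, 0.3)
  p_vals <- replicate(1000, fit_linear_qtl(sample(d), y)$p)
  expect_gt(ks.test(p_vals, "punif")$p.value, 0.01)
})

test_that("missing dosages are dropped pairwise and designs validated", {
  set.seed(4)
  d <- c(rbinom(50, 2, 0.4), NA, NA)
  y <- rnorm(52)
  fit <- fit_linear_qtl(d, y)
  expect_equal(fit$n, 50)
  expect_error(fit_linear_qtl(rep(1, 30), rnorm(30)), "collinear")
})

test_that("map_caqtls applies joint BH and honors the threshold strictly", {
  pe <- data.frame(variant_id = "var_0005", peak_id = "peak_0003", beta = 4)
  s <- sim_acc(n = 100, peaks = 10, seed = 6, planted_effects = pe)
  res <- map_caqtls(s$g, s$acc, window = 1e6, fdr_threshold = 0.05)
  expect_equal(res$fdr, p.adjust(res$p, "BH"))
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  top <- res[res$variant_id == "var_0005" & res$peak_id == "peak_0003", ]
  expect_true(top$significant)
  # threshold 0 yields no calls
  res0 <- map_caqtls(s$g, s$acc, window = 1e6, fdr_threshold = 0)
  expect_equal(sum(res0$significant), 0)
  # fast path equals the per-pair OLS route
  one <- fit_linear_qtl(s$g$dosages[, "var_0005"],
    s$acc$values["peak_0003", ])
  expect_equal(top$beta, one$beta, tolerance = 1e-10)
  expect_equal(top$se, one$se, tolerance = 1e-10)
})

test_that("map_caqtls respects covariates: planted confounder recovered", {
  set.seed(44)
  s <- sim_acc(n = 80, peaks = 8, seed = 10)
  conf <- rnorm(80)
  vals <- s$acc$values + 3 * matrix(conf, 8, 80, byrow = TRUE)
  acc <- structure(list(peaks = s$acc$peaks, values = vals),
    class = "accessibility_matrix")
  covs <- matrix(conf, 80, 1, dimnames = list(s$g$samples, "conf"))
  res <- map_caqtls(s$g, acc, covariates = covs, window = 1e6)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("lead caQTL per peak is stable under row permutation", {
  s <- sim_acc(n = 60, peaks = 10, seed = 20)
  res <- map_caqtls(s$g, s$acc, window = 1e6)
  set.seed(2)
  perm <- res[sample(nrow(res)), ]
  l1 <- lead_caqtls(res)
  l2 <- lead_caqtls(perm)
  expect_equal(l1[order(l1$peak_id), ], l2[order(l2$peak_id), ],
    ignore_attr = TRUE)
})

test_that("sample alignment is by id intersection and errors when empty", {
  s <- sim_acc(n = 30, peaks = 5, seed = 2)
  acc_renamed <- s$acc
  colnames(acc_renamed$values) <- paste0("other_", seq_len(30))
  expect_error(map_caqtls(s$g, acc_renamed), "overlapping samples")
})
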