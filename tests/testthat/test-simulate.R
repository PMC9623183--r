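test_that("generators are bit-identical given the same seed and config", {
  pe <- data.frame(variant_id = "var_0003", peak_id = "peak_0002", beta = 1)
  ms <- data.frame(variant_id = "var_0003", peak_id = "peak_0002",
    gene_id = "g1", a = 1, b = 1, c_direct = 0)
  ss <- data.frame(variant_id = "var_0003", log_hazard = 0.5)
  cfg <- sim_config(n_samples = 30, n_variants = 20, n_peaks = 5,
    planted_effects = pe, mediation_specs = ms, survival_specs = ss,
    seed = 99)
  run <- function() {
    g <- simulate_genotypes(cfg)
    a <- simulate_accessibility(g, cfg)
    e <- simulate_expression(g, a, cfg)
    s <- simulate_survival(g, cfg)
    t <- simulate_state_track(cfg)
    list(g$dosages, a$values, a$peaks, e$values, s, t$intervals)
  }
  expect_identical(run(), run())
  m1 <- simulate_motif_locus(10, seed = 5)
  m2 <- simulate_motif_locus(10, seed = 5)
  expect_identical(m1, m2)
})

test_that("unlinked variants are empirically uncorrelated, blocks are correlated", {
  cfg0 <- sim_config(n_samples = 2000, n_variants = 30, ld_block_size = 10,
    ld_rho = 0, seed = 3)
  g0 <- simulate_genotypes(cfg0)
  cc <- cor(g0$dosages)^2
  expect_lt(mean(cc[upper.tri(cc)]), 0.02)
  cfg9 <- sim_config(n_samples = 1000, n_variants = 30, ld_block_size = 10,
    ld_rho = 0.9, seed = 3)
  g9 <- simulate_genotypes(cfg9)
  adjacent_same_block <- function(dos) {
    r2 <- numeric(0)
    for (j in 2:ncol(dos)) {
      if ((j - 1) %% 10 != 0) r2 <- c(r2, cor(dos[, j - 1], dos[, j])^2)
    }
    r2
  }
  expect_gt(mean(adjacent_same_block(g9$dosages)), 0.4)
})

test_that("simulated genotypes hit the target MAF and satisfy HWE", {
  cfg <- sim_config(n_samples = 5000, n_variants = 100,
    maf_range = c(0.3, 0.3), seed = 21)
  g <- simulate_genotypes(cfg)
  mafs <- apply(g$dosages, 2, compute_maf)
  expect_true(all(abs(mafs - 0.3) < 0.02))
  hwe_ps <- apply(g$dosages, 2, function(v) {
    hwe_exact_test(sum(v == 0), sum(v == 1), sum(v == 2))
  })
  expect_gte(mean(hwe_ps > 0.001), 0.95)
})

test_that("null accessibility gives uniform association p-values", {
  cfg <- sim_config(n_samples = 100, n_variants = 100, n_peaks = 10,
    noise_sd = 1, seed = 13)
  g <- simulate_genotypes(cfg)
  a <- simulate_accessibility(g, cfg)
  p_vals <- as.vector(vapply(seq_len(100), function(v) {
    vapply(seq_len(10), function(pk) {
      fit_linear_qtl(g$dosages[, v], a$values[pk, ])$p
    }, 0.0)
  }, numeric(10)))
  expect_gt(ks.test(p_vals, "punif")$p.value, 0.01)
})

test_that("planted accessibility effects are recovered", {
  # near-noiseless: slope equals the planted beta
  pe <- data.frame(variant_id = "var_0001", peak_id = "peak_0001", beta = 1)
  cfg <- sim_config(n_samples = 50, n_variants = 5, n_peaks = 3,
    planted_effects = pe, noise_sd = 1e-9, seed = 5)
  g <- simulate_genotypes(cfg)
  a <- simulate_accessibility(g, cfg)
  fit <- fit_linear_qtl(g$dosages[, "var_0001"], a$values["peak_0001", ])
  expect_lt(abs(fit$beta - 1), 1e-6)
  # sampling-noise regime: slope within 3 SE of truth in nearly all draws
  hits <- vapply(1:200, function(i) {
    cfg_i <- sim_config(n_samples = 300, n_variants = 5, n_peaks = 3,
      planted_effects = data.frame(variant_id = "var_0001",
        peak_id = "peak_0001", beta = 0.5),
      maf_range = c(0.3, 0.3), noise_sd = 1, seed = 1000 + i)
    g_i <- simulate_genotypes(cfg_i)
    a_i <- simulate_accessibility(g_i, cfg_i)
    f <- fit_linear_qtl(g_i$dosages[, "var_0001"], a_i$values["peak_0001", ])
    abs(f$beta - 0.5) <= 3 * f$se
  }, TRUE)
  expect_gte(mean(hits), 0.99)
})

test_that("expression carries the planted mediation structure", {
  ms <- data.frame(variant_id = "var_0001", peak_id = "peak_0001",
    gene_id = "g1", a = 2, b = 3, c_direct = 0)
  pe <- data.frame(variant_id = "var_0001", peak_id = "peak_0001", beta = 2)
  cfg <- sim_config(n_samples = 500, n_variants = 5, n_peaks = 3,
    planted_effects = pe, mediation_specs = ms, noise_sd = 0.01, seed = 2)
  g <- simulate_genotypes(cfg)
  a <- simulate_accessibility(g, cfg)
  e <- simulate_expression(g, a, cfg)
  fit <- fit_mediation(g$dosages[, "var_0001"], a$values["peak_0001", ],
    e$values["g1", ])
  expect_lt(abs(fit$acme - 6), 0.2)
  expect_lt(abs(fit$ade - 0), 0.2)
  # direct-only gene: ACME vanishes
  ms2 <- data.frame(variant_id = "var_0001", peak_id = "peak_0001",
    gene_id = "g1", a = 0, b = 0, c_direct = 2)
  cfg2 <- sim_config(n_samples = 400, n_variants = 5, n_peaks = 3,
    mediation_specs = ms2, noise_sd = 0.1, seed = 2)
  g2 <- simulate_genotypes(cfg2)
  a2 <- simulate_accessibility(g2, cfg2)
  e2 <- simulate_expression(g2, a2, cfg2)
  fit2 <- fit_mediation(g2$dosages[, "var_0001"], a2$values["peak_0001", ],
    e2$values["g1", ])
  expect_lt(abs(fit2$acme), 0.02)
  expect_lt(abs(fit2$ade - 2), 0.1)
  expect_lt(abs(fit2$te - fit2$acme - fit2$ade), 1e-8)
})

test_that("survival generator honors censoring and hazards", {
  cfg0 <- sim_config(n_samples = 200, n_variants = 5, censor_rate = 0, seed = 4)
  g <- simulate_genotypes(cfg0)
  s0 <- simulate_survival(g, cfg0)
  expect_true(all(s0$event == 1))
  expect_true(all(s0$time_days > 0))
  cfg5 <- sim_config(n_samples = 400, n_variants = 5, censor_rate = 0.5, seed = 4)
  s5 <- simulate_survival(simulate_genotypes(cfg5), cfg5)
  expect_gt(mean(s5$event == 0), 0.4)
  expect_lt(mean(s5$event == 0), 0.6)
})

test_that("motif locus: 61-mers differing only at the centered variant, loss call", {
  loc <- simulate_motif_locus(12, seed = 8)
  expect_equal(nchar(loc$ref_sequence), 61)
  expect_equal(nchar(loc$alt_sequence), 61)
  diffs <- which(strsplit(loc$ref_sequence, "")[[1]] !=
    strsplit(loc$alt_sequence, "")[[1]])
  expect_equal(diffs, loc$variant_pos)
  ds <- disruption_score(loc$ref_sequence, loc$alt_sequence, loc$pwm,
    loc$variant_pos)
  expect_false(is.null(ds))
  expect_equal(ds$direction, "loss")
  expect_gt(ds$log_ratio, 0)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(censor_rate = 1.2), "censor_rate")
  expect_error(
    sim_config(n_variants = 5, planted_effects = data.frame(
      variant_id = "var_9999", peak_id = "peak_0001", beta = 1)),
    "variant_id")
  expect_error(simulate_motif_locus(3, 1), "pwm_width")
})
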