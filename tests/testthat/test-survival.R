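test_that("genotype groupings follow the three genetic models", {
  d <- c(0, 1, 2)
  expect_equal(as.integer(table(assign_groups(d, "dominant"))), c(1, 2))
  expect_equal(as.integer(table(assign_groups(d, "recessive"))), c(2, 1))
  expect_equal(as.integer(table(assign_groups(c(0, 0, 1, 2), "additive"))),
    c(2, 1, 1))
  # alt-major variants are recoded to minor-allele counts
  g_flip <- assign_groups(c(2, 2, 2, 1, 0), "dominant")
  expect_true(attr(g_flip, "recoded"))
  # 2,2,2 recode to 0 = major homs; 1 stays het; 0 becomes 2
  expect_equal(as.integer(table(g_flip)), c(3, 2))
  mono <- assign_groups(c(2, 2, 2), "additive")
  expect_false(attr(mono, "testable"))
  # partitions always sum to the cohort size
  set.seed(3)
  for (i in 1:20) {
    d_i <- rbinom(30, 2, runif(1, 0.1, 0.9))
    for (m in c("dominant", "recessive", "additive")) {
      expect_equal(sum(table(assign_groups(d_i, m))), 30)
    }
  }
})

test_that("log-rank: identical groups, hand-worked 4-donor instance", {
  surv <- data.frame(donor = sprintf("d%d", 1:8),
    time_days = rep(c(10, 20, 30, 40), 2), event = 1)
  dup_groups <- factor(rep(c("a", "b"), each = 4))
  lr <- logrank_test(surv, dup_groups)
  expect_equal(lr$chi2, 0, tolerance = 1e-10)
  expect_equal(lr$p, 1, tolerance = 1e-10)
  # hand computation: times 1..4 all events, groups A A B B
  # t=1: E_A=1/2, V=1/4; t=2: E_A=1/3, V=2/9; afterwards no A at risk
  # O_A=2, E_A=5/6, V=17/36 -> chi2 = (7/6)^2 / (17/36) = 49/17
  surv4 <- data.frame(donor = sprintf("d%d", 1:4), time_days = 1:4, event = 1)
  g4 <- factor(c("A", "A", "B", "B"))
  lr4 <- logrank_test(surv4, g4)
  expect_equal(lr4$chi2, 49 / 17, tolerance = 1e-10)
  expect_equal(lr4$df, 1)
  # internal consistency: chi2 equals the squared standardized statistic
  expect_equal(lr4$chi2,
    (lr4$obs[1] - lr4$exp[1])^2 / lr4$var[1, 1], tolerance = 1e-10)
  # chi2 is invariant under monotone time transforms
  surv4b <- surv4
  surv4b$time_days <- exp(surv4$time_days / 2)
  expect_equal(logrank_test(surv4b, g4)$chi2, lr4$chi2, tolerance = 1e-12)
  # untestable cases are flagged, not errors
  expect_false(logrank_test(surv4, factor(rep("A", 4)))$testable)
  surv0 <- surv4
  surv0$event <- 0
  expect_false(logrank_test(surv0, g4)$testable)
})

test_that("log-rank power: hazard ratio 3 detected at n = 200", {
  rejected <- vapply(1:100, function(i) {
    set.seed(i)
    grp <- rep(0:1, each = 100)
    time <- rexp(200, rate = 0.001 * 3^grp)
    surv <- data.frame(donor = sprintf("d%d", 1:200), time_days = time,
      event = 1)
    logrank_test(surv, factor(grp))$p < 0.01
  }, TRUE)
  expect_gte(mean(rejected), 0.95)
})

test_that("hazard ratio: identity, inversion, recovery of a true HR of 2", {
  surv <- data.frame(donor = sprintf("d%d", 1:8),
    time_days = rep(c(10, 20, 30, 40), 2), event = 1)
  dup_groups <- factor(rep(c("a", "b"), each = 4))
  hr_same <- hazard_ratio(surv, dup_groups)
  expect_equal(hr_same$hr, 1, tolerance = 1e-10)
  set.seed(17)
  grp <- rep(0:1, each = 300)
  time <- rexp(600, rate = 0.001 * 2^grp)
  sv <- data.frame(donor = sprintf("d%d", 1:600), time_days = time, event = 1)
  h <- hazard_ratio(sv, factor(grp))
  expect_true(h$hr > 1.5 && h$hr < 2.7)
  expect_true(h$ci_low < h$hr && h$hr < h$ci_high)
  # swapping group labels inverts the ratio
  h_sw <- hazard_ratio(sv, factor(1 - grp))
  expect_equal(h_sw$hr, 1 / h$hr, tolerance = 1e-9)
  # simulated HR 2 recovered within the band in most replicates
  hits <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    t_i <- rexp(600, rate = 0.001 * 2^grp)
    s_i <- data.frame(donor = sprintf("d%d", 1:600), time_days = t_i,
      event = 1)
    h_i <- hazard_ratio(s_i, factor(grp))$hr
    h_i >= 1.5 && h_i <= 2.7
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("survival scan emits one row per variant-model with coherent sizes", {
  ss <- data.frame(variant_id = "var_0001", log_hazard = log(2.5))
  cfg <- sim_config(n_samples = 300, n_variants = 8, survival_specs = ss,
    censor_rate = 0.2, maf_range = c(0.3, 0.5), seed = 55)
  g <- simulate_genotypes(cfg)
  sv <- simulate_survival(g, cfg)
  res <- suppressMessages(survival_scan(genotypes = g, surv = sv))
  expect_equal(nrow(res), 8 * 3)
  sizes <- strsplit(res$group_sizes, "/")
  expect_true(all(vapply(sizes, function(x) sum(as.integer(x)), 0) == 300))
  planted <- res[res$variant_id == "var_0001", ]
  expect_true(all(planted$p < 0.05))
  # alpha 0 flags nothing
  res0 <- suppressMessages(survival_scan(genotypes = g, surv = sv, alpha = 0))
  expect_equal(sum(res0$significant), 0)
})

test_that("a planted dominant effect favors the dominant model over additive", {
  wins <- vapply(1:40, function(i) {
    set.seed(3000 + i)
    n <- 250
    d <- rbinom(n, 2, 0.35)
    carrier <- as.integer(d > 0) # pure dominant effect
    time <- rexp(n, rate = 0.001 * 2.2^carrier)
    sv <- data.frame(donor = sprintf("d%d", 1:n), time_days = time, event = 1)
    g <- toy_genotypes(matrix(d, ncol = 1))
    sv$donor <- g$samples
    res <- suppressMessages(survival_scan(genotypes = g, surv = sv,
      models = c("additive", "dominant")))
    res$p[res$model == "dominant"] < res$p[res$model == "additive"]
  }, TRUE)
  expect_gte(mean(wins), 0.6)
})

test_that("null survival scan rejects near the nominal rate", {
  set.seed(91)
  n <- 200
  rates <- vapply(1:300, function(i) {
    d <- rbinom(n, 2, 0.3)
    time <- rexp(n, 0.001)
    cens <- runif(n) < 0.2
    sv <- data.frame(donor = sprintf("d%d", 1:n),
      time_days = ifelse(cens, time * runif(n), time),
      event = as.integer(!cens))
    g <- assign_groups(d, "dominant")
    logrank_test(sv, g)$p < 0.05
  }, TRUE)
  expect_gte(mean(rates), 0.02)
  expect_lte(mean(rates), 0.09)
})

test_that("KM tables are valid step functions per group", {
  set.seed(5)
  sv <- data.frame(donor = sprintf("d%d", 1:60),
    time_days = rexp(60, 0.01), event = rbinom(60, 1, 0.8))
  g <- factor(rep(c("x", "y"), 30))
  km <- km_table(sv, g)
  expect_setequal(unique(km$group), c("x", "y"))
  for (gr in c("x", "y")) {
    s <- km$survival[km$group == gr]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
})
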