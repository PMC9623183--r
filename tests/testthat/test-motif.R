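random_pwm <- function(w, seed, informative = TRUE) {
  set.seed(seed)
  counts <- matrix(rexp(4 * w, if (informative) 0.2 else 1), 4, w)
  if (informative) {
    for (j in seq_len(w)) counts[sample(4, 1), j] <- counts[, j] |> sum() * 3
  }
  pwm(round(counts * 10), motif_id = sprintf("rnd_w%d_s%d", w, seed))
}

consensus_seq <- function(x) {
  paste(c("A", "C", "G", "T")[apply(x$probabilities, 2, which.max)],
    collapse = "")
}

embed_at <- function(core, pos, len = 61, seed = 1) {
  set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  s[pos:(pos + nchar(core) - 1)] <- strsplit(core, "")[[1]]
  paste(s, collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

test_that("match p-value: single-base motif and boundary behavior", {
  m <- pwm(matrix(c(97, 1, 1, 1), 4, 1), pseudocount = 0)
  # only A scores above 0; uniform background puts 1/4 of mass there
  a_score <- m$llr["A", 1]
  expect_equal(pwm_match_pvalue(m, a_score), 0.25, tolerance = 1e-9)
  # at or below the minimum achievable score the p-value is 1
  w5 <- random_pwm(5, seed = 2)
  min_score <- sum(apply(w5$llr, 2, min))
  expect_equal(pwm_match_pvalue(w5, min_score), 1)
  expect_equal(pwm_match_pvalue(w5, min_score - 10), 1)
  # monotone nonincreasing in the score
  scores <- seq(min_score, sum(apply(w5$llr, 2, max)), length.out = 50)
  ps <- vapply(scores, function(s) pwm_match_pvalue(w5, s), 0.0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("DP match p-values agree with exhaustive enumeration for widths <= 8", {
  for (w in 4:8) {
    x <- random_pwm(w, seed = w * 7)
    set.seed(w)
    # probe at the scores of random words plus the extremes
    probes <- c(
      sum(apply(x$llr, 2, max)),
      replicate(20, sum(x$llr[cbind(sample(4, w, TRUE), 1:w)]))
    )
    for (s in probes) {
      expect_lt(
        abs(pwm_match_pvalue(x, s) - oracle_pwm_pvalue(x$llr, x$background, s)),
        1e-3
      )
    }
  }
})

test_that("best overlapping hit finds planted consensus on either strand", {
  x <- random_pwm(10, seed = 42)
  cons <- consensus_seq(x)
  sq <- embed_at(cons, 25, seed = 3) # spans positions 25..34, covers 31
  hit <- best_overlapping_hit(sq, x)
  expect_equal(hit$offset, 25)
  expect_equal(hit$strand, "+")
  # reverse-complemented sequence: same p on the opposite strand
  hit_rc <- best_overlapping_hit(revcomp(sq), x)
  expect_equal(hit_rc$p, hit$p, tolerance = 1e-12)
  expect_equal(hit_rc$strand, "-")
  # stronger hit NOT covering the variant is ignored; weaker overlapping
  # runner-up wins
  x2 <- random_pwm(8, seed = 9)
  cons2 <- consensus_seq(x2)
  weak <- sub("^.", if (substr(cons2, 1, 1) == "A") "C" else "A", cons2)
  sq2 <- embed_at(cons2, 2, seed = 5)       # perfect match far from center
  sq2 <- sub(substr(sq2, 28, 35), weak, sq2, fixed = TRUE)
  chars <- strsplit(embed_at(cons2, 2, seed = 5), "")[[1]]
  chars[28:35] <- strsplit(weak, "")[[1]]
  sq2 <- paste(chars, collapse = "")
  hit2 <- best_overlapping_hit(sq2, x2)
  expect_true(hit2$offset >= 24 && hit2$offset <= 31)
  full <- best_overlapping_hit(embed_at(cons2, 27, seed = 5), x2)
  expect_gte(hit2$p, full$p)
  # sequence of the wrong length is rejected
  expect_error(best_overlapping_hit("ACGT", x), "length")
})

test_that("disruption scoring: planted loss, label swap symmetry, strand flip", {
  loc <- simulate_motif_locus(10, seed = 77)
  ds <- disruption_score(loc$ref_sequence, loc$alt_sequence, loc$pwm,
    loc$variant_pos)
  expect_equal(ds$direction, "loss")
  expect_gt(ds$log_ratio, 0)
  expect_lt(ds$p_ref, ds$p_alt)
  # swapping the allele labels flips the direction, keeps the magnitude
  ds_sw <- disruption_score(loc$alt_sequence, loc$ref_sequence, loc$pwm,
    loc$variant_pos)
  expect_equal(ds_sw$direction, "gain")
  expect_equal(ds_sw$log_ratio, ds$log_ratio, tolerance = 1e-12)
  # flipping both alleles to the other strand preserves call and magnitude
  ds_rc <- disruption_score(revcomp(loc$ref_sequence),
    revcomp(loc$alt_sequence), loc$pwm, loc$variant_pos)
  expect_equal(ds_rc$direction, ds$direction)
  expect_equal(ds_rc$log_ratio, ds$log_ratio, tolerance = 1e-12)
  # no hit below threshold -> NULL
  weak_pwm <- pwm(matrix(25, 4, 6), motif_id = "flat")
  expect_null(disruption_score(loc$ref_sequence, loc$alt_sequence, weak_pwm,
    loc$variant_pos))
  # multi-base differences are rejected
  bad_alt <- paste0("AA", substr(loc$alt_sequence, 3, 61))
  expect_error(disruption_score(loc$ref_sequence, bad_alt, loc$pwm,
    loc$variant_pos), "variant position")
})

test_that("log_ratio is nonnegative across random disrupted loci", {
  for (i in 1:25) {
    loc <- simulate_motif_locus(4 + i %% 10, seed = 900 + i)
    ds <- disruption_score(loc$ref_sequence, loc$alt_sequence, loc$pwm,
      loc$variant_pos)
    if (!is.null(ds)) expect_gte(ds$log_ratio, 0)
  }
})

test_that("motif-caQTL association: cross product, separation, null", {
  # forced 2x2
  flags <- matrix(c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 10),
    rep(FALSE, 30)), ncol = 1, dimnames = list(NULL, "m1"))
  caqtl <- c(rep(TRUE, 40), rep(FALSE, 40))
  res <- motif_caqtl_association(flags, caqtl)
  expect_equal(res$or, 9)
  # complete separation: corrected OR finite
  flags2 <- matrix(c(rep(TRUE, 20), rep(FALSE, 20)), ncol = 1,
    dimnames = list(NULL, "m1"))
  caqtl2 <- c(rep(TRUE, 20), rep(FALSE, 20))
  res2 <- motif_caqtl_association(flags2, caqtl2)
  expect_true(is.finite(res2$or))
  expect_gt(res2$or, 100)
  # independence: log OR centered near zero across motifs
  set.seed(10)
  flags3 <- matrix(runif(200 * 20) < 0.4, 200, 20,
    dimnames = list(NULL, sprintf("m%d", 1:20)))
  caqtl3 <- runif(200) < 0.5
  res3 <- motif_caqtl_association(flags3, caqtl3)
  expect_lt(abs(mean(log(res3$or))), 0.3)
  expect_error(motif_caqtl_association(flags3, rep(TRUE, 200)), "non-caQTL")
})

test_that("accessibility concordance: planted concordant regime vs null", {
  set.seed(31)
  n <- 200
  # concordant: stronger-match allele (gain = alt stronger) opens chromatin
  dirs <- sample(c("gain", "loss"), n, replace = TRUE)
  betas_conc <- ifelse(dirs == "gain", abs(rnorm(n)), -abs(rnorm(n)))
  d <- data.frame(variant_id = sprintf("v%d", 1:n), motif_id = "mA",
    direction = dirs)
  q <- data.frame(variant_id = d$variant_id, beta = betas_conc)
  res <- accessibility_concordance(d, q)
  expect_gte(res$fraction_concordant, 0.9)
  # independent assignment: fraction near one half
  q_null <- data.frame(variant_id = d$variant_id, beta = rnorm(n))
  res_null <- accessibility_concordance(d, q_null)
  expect_lt(abs(res_null$fraction_concordant - 0.5), 0.1)
  # single record: fraction is 0 or 1
  res1 <- accessibility_concordance(d[1, ], q[1, ])
  expect_true(res1$fraction_concordant %in% c(0, 1))
})

test_that("JASPAR round trip preserves the matrix", {
  x <- random_pwm(7, seed = 55)
  path <- withr::local_tempfile(fileext = ".pfm")
  write_jaspar_pfm(x, path)
  back <- read_jaspar_pfm(path)[[1]]
  expect_equal(back$counts, x$counts, ignore_attr = TRUE)
  expect_equal(back$probabilities, x$probabilities, tolerance = 1e-12)
})
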