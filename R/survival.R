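## Genotype-stratified survival: additive / dominant / recessive group
## codings, k-sample log-rank tests (survdiff engine), an O-E/V hazard
## ratio for two-group codings, Kaplan-Meier step tables, and the
## variant-by-model scan.

#' Genotype group assignment under a genetic model
#'
#' Dosages are recoded to minor-allele counts within the analyzed cohort
#' (a `recoded` attribute records a flip). Additive keeps the three
#' genotype groups; dominant merges heterozygotes with minor-allele
#' homozygotes against major-allele homozygotes; recessive merges
#' heterozygotes with major-allele homozygotes against minor-allele
#' homozygotes.
#'
#' @param dosages alt-allele dosage vector (0/1/2/NA).
#' @param model one of "additive", "dominant", "recessive".
#' @return factor of group labels (NA for missing dosage), with
#'   attributes `recoded` and `testable` (FALSE when only one group is
#'   populated).
#' @export
assign_groups <- function(dosages, model = c("additive", "dominant", "recessive")) {
  model <- match.arg(model)
  d <- dosages
  recoded <- FALSE
  f_alt <- mean(d, na.rm = TRUE) / 2
  if (!is.nan(f_alt) && f_alt > 0.5) {
    d <- 2 - d
    recoded <- TRUE
  }
  lab <- switch(model,
    additive = factor(d, levels = 0:2, labels = c("AA", "Aa", "aa")),
    dominant = factor(ifelse(d == 0, "AA", "Aa_aa"),
      levels = c("AA", "Aa_aa")),
    recessive = factor(ifelse(d == 2, "aa", "AA_Aa"),
      levels = c("AA_Aa", "aa"))
  )
  lab <- droplevels(lab)
  attr(lab, "recoded") <- recoded
  attr(lab, "testable") <- nlevels(lab) >= 2
  lab
}

#' k-sample log-rank test
#'
#' Standard log-rank: at each event time, observed versus
#' hypergeometric-expected events per group, chi-square with k - 1 df
#' (ties handled by the usual multiple-event correction). Wraps
#' `survival::survdiff`.
#'
#' @param surv data.frame donor, time_days, event.
#' @param groups factor aligned with `surv` rows; NA rows are dropped.
#' @return list(chi2, df, p, n, group_sizes, obs, exp, var) or a flagged
#'   untestable result when < 2 populated groups or no events.
#' @export
logrank_test <- function(surv, groups) {
  ok <- !is.na(groups)
  time <- surv$time_days[ok]
  event <- surv$event[ok]
  g <- droplevels(factor(groups[ok]))
  if (nlevels(g) < 2) {
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
      n = length(time), group_sizes = table(g), testable = FALSE,
      reason = "fewer than 2 populated groups"))
  }
  if (sum(event) == 0) {
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
      n = length(time), group_sizes = table(g), testable = FALSE,
      reason = "no events"))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- nlevels(g) - 1
  list(
    chi2 = sd_$chisq, df = df, p = pchisq(sd_$chisq, df, lower.tail = FALSE),
    n = length(time), group_sizes = table(g),
    obs = sd_$obs, exp = sd_$exp,
    var = if (is.matrix(sd_$var)) sd_$var else matrix(sd_$var),
    testable = TRUE
  )
}

#' Log-rank hazard ratio for two groups
#'
#' ln HR of the second group versus the first from the log-rank
#' quantities: (O2 - E2) / V with V the log-rank variance; 95% CI
#' exp(ln HR +/- 1.96 / sqrt(V)). An approximation to the partial-
#' likelihood estimate, derived from the same statistic as the test.
#'
#' @param surv data.frame donor, time_days, event.
#' @param groups two-level factor.
#' @return list(hr, ci_low, ci_high, ln_hr, v) or flagged result when
#'   undefined (zero variance, missing events).
#' @export
hazard_ratio <- function(surv, groups) {
  lr <- logrank_test(surv, groups)
  if (!isTRUE(lr$testable)) {
    return(list(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      defined = FALSE, reason = lr$reason))
  }
  if (length(lr$obs) != 2) abort("hazard ratio requires exactly 2 groups")
  v <- lr$var[1, 1]
  if (!is.finite(v) || v <= 0) {
    return(list(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      defined = FALSE, reason = "zero log-rank variance"))
  }
  ln_hr <- (lr$obs[2] - lr$exp[2]) / v
  list(
    hr = exp(ln_hr),
    ci_low = exp(ln_hr - 1.96 / sqrt(v)),
    ci_high = exp(ln_hr + 1.96 / sqrt(v)),
    ln_hr = ln_hr, v = v, defined = TRUE
  )
}

#' Kaplan-Meier step-function table
#'
#' @param surv data.frame donor, time_days, event.
#' @param groups factor aligned with `surv`.
#' @return data.frame group, time, survival, n_risk, n_event.
#' @export
km_table <- function(surv, groups) {
  ok <- !is.na(groups)
  g <- droplevels(factor(groups[ok]))
  fit <- survival::survfit(
    survival::Surv(surv$time_days[ok], surv$event[ok]) ~ g)
  strata <- if (is.null(fit$strata)) {
    rep(levels(g)[1], length(fit$time))
  } else {
    rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  data.frame(
    group = strata, time = fit$time, survival = fit$surv,
    n_risk = fit$n.risk, n_event = fit$n.event, stringsAsFactors = FALSE
  )
}

#' Survival scan across variants and genetic models
#'
#' One log-rank test per (variant, model); two-group models also report
#' the O-E/V hazard ratio. Donors are aligned by id intersection.
#'
#' @param variant_ids variants to scan (default: all in `genotypes`).
#' @param genotypes a [genotype_matrix()].
#' @param surv data.frame donor, time_days, event.
#' @param models subset of additive/dominant/recessive.
#' @param alpha significance threshold on the log-rank p (default 0.05).
#' @return data.frame: variant_id, model, n, group sizes, chi2, df, p,
#'   hr, hr_ci_low, hr_ci_high, significant, testable.
#' @export
survival_scan <- function(variant_ids = NULL, genotypes, surv,
                          models = c("additive", "dominant", "recessive"),
                          alpha = 0.05) {
  donors <- intersect(genotypes$samples, surv$donor)
  if (length(donors) == 0) abort("no donors shared between genotypes and survival table")
  surv <- surv[match(donors, surv$donor), ]
  if (is.null(variant_ids)) variant_ids <- genotypes$variants$id
  rows <- list()
  for (v in variant_ids) {
    dos <- genotypes$dosages[donors, v]
    for (mdl in models) {
      g <- assign_groups(dos, mdl)
      lr <- logrank_test(surv, g)
      hr <- if (isTRUE(lr$testable) && nlevels(droplevels(g[!is.na(g)])) == 2) {
        hazard_ratio(surv, g)
      } else {
        list(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
      }
      rows[[length(rows) + 1]] <- data.frame(
        variant_id = v, model = mdl, n = lr$n,
        group_sizes = paste(as.integer(lr$group_sizes), collapse = "/"),
        chi2 = lr$chi2, df = lr$df, p = lr$p,
        hr = hr$hr, hr_ci_low = hr$ci_low, hr_ci_high = hr$ci_high,
        significant = isTRUE(lr$testable) && !is.na(lr$p) && lr$p < alpha,
        testable = isTRUE(lr$testable), stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  n_sig <- length(unique(res$variant_id[res$significant]))
  message(sprintf("survival scan: %d variant(s) significant at alpha = %g in >= 1 model",
    n_sig, alpha))
  res
}
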