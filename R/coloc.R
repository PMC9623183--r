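## caQTL-eQTL colocalization: two-step candidate pairing by lead-SNP LD,
## then the Bayesian posterior over shared-causal configurations built
## from per-variant Wakefield approximate Bayes factors.

#' Log Wakefield approximate Bayes factor
#'
#' For an estimate beta with standard error se and effect prior
#' N(0, prior_sd^2): with V = se^2, z = beta / se and
#' r = W / (V + W), log ABF = 0.5 * log(1 - r) + 0.5 * z^2 * r
#' (alternative vs null). Vectorized over beta/se.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), > 0.
#' @param prior_sd prior effect SD (default 0.15, the standard
#'   quantitative-trait choice).
#' @return log approximate Bayes factor(s).
#' @export
wakefield_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) abort("standard errors must be positive")
  if (prior_sd <= 0) abort("prior_sd must be positive")
  V <- se^2
  W <- prior_sd^2
  z <- beta / se
  r <- W / (V + W)
  0.5 * log(1 - r) + 0.5 * z^2 * r
}

#' Colocalization posterior over causal configurations
#'
#' Enumeration-based posterior over the five hypotheses: H0 no
#' association, H1 causal variant for trait 1 only, H2 for trait 2 only,
#' H3 two distinct causal variants, H4 one shared causal variant.
#' Per-variant log ABFs feed configuration sums evaluated in log space
#' with log-sum-exp; priors are per-variant (p1, p2) and per-shared-
#' variant (p12).
#'
#' @param stats_ca,stats_e data.frames with columns variant_id, beta, se
#'   and (recommended) per-variant sample size n, aligned to the same
#'   variant list (same order). When n is present each trait's stats are
#'   put on the standardized scale (beta = z / sqrt(n), se = 1 / sqrt(n))
#'   before the ABF, so the prior SD applies to standardized effects and
#'   the posteriors are invariant to the phenotype's measurement units;
#'   without n the stats are used as given.
#' @param p1,p2,p12 prior probabilities (defaults 1e-4, 1e-4, 1e-5).
#' @param prior_sd effect-size prior SD passed to [wakefield_abf()].
#' @return list of class `coloc_posterior`: pp0..pp4, n_snps, lead
#'   variant ids per trait.
#' @export
coloc_abf <- function(stats_ca, stats_e, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd = 0.15) {
  if (nrow(stats_ca) != nrow(stats_e) ||
      !all(stats_ca$variant_id == stats_e$variant_id)) {
    abort("variant lists must be aligned across the two traits")
  }
  if (nrow(stats_ca) < 2) abort("need at least 2 shared variants")
  standardize <- function(s) {
    if (!"n" %in% names(s)) return(s)
    z <- s$beta / s$se
    s$beta <- z / sqrt(s$n)
    s$se <- 1 / sqrt(s$n)
    s
  }
  stats_ca <- standardize(stats_ca)
  stats_e <- standardize(stats_e)
  l1 <- wakefield_abf(stats_ca$beta, stats_ca$se, prior_sd)
  l2 <- wakefield_abf(stats_e$beta, stats_e$se, prior_sd)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  lH0 <- 0
  lH1 <- log(p1) + s1
  lH2 <- log(p2) + s2
  ## H3: distinct pairs = (sum_i ABF1_i)(sum_j ABF2_j) - sum_i ABF1_i ABF2_i
  lH3 <- log(p1) + log(p2) + logdiffexp(s1 + s2, s12)
  lH4 <- log(p12) + s12
  lh <- c(lH0, lH1, lH2, lH3, lH4)
  pp <- exp(lh - logsumexp(lh))
  structure(list(
    pp0 = pp[1], pp1 = pp[2], pp2 = pp[3], pp3 = pp[4], pp4 = pp[5],
    n_snps = nrow(stats_ca),
    lead_trait1 = stats_ca$variant_id[which.max(l1)],
    lead_trait2 = stats_e$variant_id[which.max(l2)]
  ), class = "coloc_posterior")
}

#' @export
print.coloc_posterior <- function(x, ...) {
  cat(sprintf(
    "coloc posterior over %d SNPs: PP0=%.3f PP1=%.3f PP2=%.3f PP3=%.3f PP4=%.3f\n",
    x$n_snps, x$pp0, x$pp1, x$pp2, x$pp3, x$pp4))
  invisible(x)
}

#' Select candidate peak-gene pairs for colocalization
#'
#' Two-step pairing: per caQTL peak, take the lead caQTL (min-p variant
#' among its significant records); collect genes whose significant eQTL
#' set contains that variant; when several genes qualify, keep the
#' gene(s) whose own lead eQTL SNP has the highest r-squared with the
#' lead caQTL SNP (exact ties all kept and flagged). Each retained pair
#' carries the intersection of variants tested for both the peak and the
#' gene.
#'
#' @param caqtl_results,eqtl_results association tables from
#'   [map_caqtls()]; the eQTL table uses `gene_id` (or `peak_id`) for the
#'   gene column.
#' @param genotypes a [genotype_matrix()] covering the lead SNPs.
#' @return list of pairs: peak_id, gene_id, lead_caqtl, lead_eqtl,
#'   ld_r2, tie flag, shared_variants.
#' @export
select_coloc_pairs <- function(caqtl_results, eqtl_results, genotypes) {
  if (nrow(caqtl_results) == 0 || nrow(eqtl_results) == 0) {
    abort("both association tables must be nonempty")
  }
  eq <- eqtl_results
  if (!"gene_id" %in% names(eq)) names(eq)[names(eq) == "peak_id"] <- "gene_id"
  ca_sig <- caqtl_results[caqtl_results$significant, , drop = FALSE]
  eq_sig <- eq[eq$significant, , drop = FALSE]
  if (nrow(ca_sig) == 0 || nrow(eq_sig) == 0) return(list())
  leads_ca <- lead_caqtls(ca_sig)
  eq_leads <- eq_sig[order(eq_sig$gene_id, eq_sig$p, abs(eq_sig$distance_bp),
    eq_sig$variant_id), ]
  eq_leads <- eq_leads[!duplicated(eq_leads$gene_id), ]
  pairs <- list()
  for (r in seq_len(nrow(leads_ca))) {
    peak <- leads_ca$peak_id[r]
    lead_ca <- leads_ca$variant_id[r]
    if (!lead_ca %in% genotypes$variants$id) {
      message("lead caQTL ", lead_ca, " absent from genotypes; peak ",
        peak, " skipped")
      next
    }
    genes <- unique(eq_sig$gene_id[eq_sig$variant_id == lead_ca])
    if (length(genes) == 0) next
    if (length(genes) > 1) {
      r2s <- vapply(genes, function(g) {
        lead_e <- eq_leads$variant_id[eq_leads$gene_id == g]
        if (!lead_e %in% genotypes$variants$id) return(NA_real_)
        as.numeric(ld_r2(genotypes$dosages[, lead_ca],
          genotypes$dosages[, lead_e]))
      }, 0.0)
      if (all(is.na(r2s))) next
      best <- max(r2s, na.rm = TRUE)
      genes <- genes[!is.na(r2s) & r2s == best]
      tie <- length(genes) > 1
    } else {
      tie <- FALSE
    }
    for (g in genes) {
      lead_e <- eq_leads$variant_id[eq_leads$gene_id == g]
      shared <- intersect(
        caqtl_results$variant_id[caqtl_results$peak_id == peak],
        eq$variant_id[eq$gene_id == g]
      )
      r2 <- if (lead_e %in% genotypes$variants$id) {
        as.numeric(ld_r2(genotypes$dosages[, lead_ca],
          genotypes$dosages[, lead_e]))
      } else NA_real_
      pairs[[length(pairs) + 1]] <- list(
        peak_id = peak, gene_id = g, lead_caqtl = lead_ca,
        lead_eqtl = lead_e, ld_r2 = r2, tie = tie,
        shared_variants = shared
      )
    }
  }
  pairs
}

#' Run colocalization for selected peak-gene pairs
#'
#' Convenience wrapper: for each pair from [select_coloc_pairs()],
#' aligns the two summary-statistic sets on the shared variants and runs
#' [coloc_abf()].
#'
#' @param pairs output of [select_coloc_pairs()].
#' @param caqtl_results,eqtl_results full association tables.
#' @param pp4_threshold colocalized call threshold (default 0.8).
#' @inheritParams coloc_abf
#' @return data.frame: peak_id, gene_id, lead_snp, n_snps, pp0..pp4,
#'   colocalized.
#' @export
colocalize_pairs <- function(pairs, caqtl_results, eqtl_results,
                             p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                             prior_sd = 0.15, pp4_threshold = 0.8) {
  eq <- eqtl_results
  if (!"gene_id" %in% names(eq)) names(eq)[names(eq) == "peak_id"] <- "gene_id"
  rows <- lapply(pairs, function(pr) {
    ca <- caqtl_results[caqtl_results$peak_id == pr$peak_id &
      caqtl_results$variant_id %in% pr$shared_variants, ]
    e <- eq[eq$gene_id == pr$gene_id &
      eq$variant_id %in% pr$shared_variants, ]
    ord <- pr$shared_variants
    ca <- ca[match(ord, ca$variant_id), ]
    e <- e[match(ord, e$variant_id), ]
    if (nrow(ca) < 2) return(NULL)
    keep_cols <- intersect(c("variant_id", "beta", "se", "n"), names(ca))
    cp <- coloc_abf(ca[, keep_cols],
      e[, intersect(c("variant_id", "beta", "se", "n"), names(e))],
      p1 = p1, p2 = p2, p12 = p12, prior_sd = prior_sd)
    data.frame(
      peak_id = pr$peak_id, gene_id = pr$gene_id,
      lead_snp = pr$lead_caqtl, n_snps = cp$n_snps,
      pp0 = cp$pp0, pp1 = cp$pp1, pp2 = cp$pp2, pp3 = cp$pp3, pp4 = cp$pp4,
      colocalized = cp$pp4 > pp4_threshold, stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    return(data.frame(peak_id = character(0), gene_id = character(0),
      lead_snp = character(0), n_snps = integer(0), pp0 = numeric(0),
      pp1 = numeric(0), pp2 = numeric(0), pp3 = numeric(0),
      pp4 = numeric(0), colocalized = logical(0)))
  }
  do.call(rbind, rows)
}
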