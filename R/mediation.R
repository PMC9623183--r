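## Causal mediation with linear structural equations and a nonparametric
## case-resampling bootstrap: does a variant's expression effect travel
## through chromatin accessibility?

#' Point estimates of mediation effects
#'
#' Two OLS fits: mediator ~ dosage + covariates (slope a) and
#' outcome ~ dosage + mediator + covariates (slopes c' and b). Under
#' linear no-interaction models the average causal mediation effect is
#' the product a * b, the average direct effect is c', and the total
#' effect is a * b + c' exactly.
#'
#' @param dosage,mediator,outcome aligned numeric vectors.
#' @param covariates optional samples x covariates matrix.
#' @return list(acme, ade, te, prop_mediated, a, b); `prop_mediated` is
#'   NA when |te| < 1e-12.
#' @export
fit_mediation <- function(dosage, mediator, outcome, covariates = NULL) {
  ok <- !is.na(dosage) & !is.na(mediator) & !is.na(outcome)
  if (!is.null(covariates)) ok <- ok & complete.cases(covariates)
  d <- dosage[ok]; m <- mediator[ok]; y <- outcome[ok]
  C <- if (!is.null(covariates)) as.matrix(covariates)[ok, , drop = FALSE] else NULL
  n <- length(d)
  p <- 2 + (if (is.null(C)) 0 else ncol(C))
  if (n <= p + 3) abort("too few samples (%d) for mediation fit", n)
  Xm <- cbind(1, d, C)
  Xy <- cbind(1, d, m, C)
  if (qr(Xy)$rank < ncol(Xy)) abort("rank-deficient mediation design")
  cm <- qr.coef(qr(Xm), m)
  cy <- qr.coef(qr(Xy), y)
  a <- cm[2]; c_prime <- cy[2]; b <- cy[3]
  acme <- a * b
  te <- acme + c_prime
  list(
    acme = unname(acme), ade = unname(c_prime), te = unname(te),
    prop_mediated = if (abs(te) < 1e-12) NA_real_ else unname(acme / te),
    a = unname(a), b = unname(b)
  )
}

## vectorized (no-covariate) mediation slopes for a block of bootstrap
## resamples; idx is an n x B matrix of row indices
mediation_boot_block <- function(d, m, y, idx) {
  n <- nrow(idx)
  D <- matrix(d[idx], n); M <- matrix(m[idx], n); Y <- matrix(y[idx], n)
  sd_ <- colMeans(D); sm <- colMeans(M); sy <- colMeans(Y)
  Dc <- sweep(D, 2, sd_); Mc <- sweep(M, 2, sm); Yc <- sweep(Y, 2, sy)
  sdd <- colSums(Dc^2)
  a <- colSums(Dc * Mc) / sdd
  ## outcome ~ 1 + d + m: 2x2 normal equations on centered data
  smm <- colSums(Mc^2)
  sdm <- colSums(Dc * Mc)
  sdy <- colSums(Dc * Yc)
  smy <- colSums(Mc * Yc)
  det <- sdd * smm - sdm^2
  c_prime <- (smm * sdy - sdm * smy) / det
  b <- (sdd * smy - sdm * sdy) / det
  cbind(acme = a * b, ade = c_prime, te = a * b + c_prime)
}

#' Bootstrap mediation analysis
#'
#' Case-resampling bootstrap of (dosage, mediator, outcome) triples:
#' percentile 95% intervals and two-sided sign-based p-values with a +1
#' continuity correction, floored at 2/(n_boot + 1). Resamples with a
#' constant dosage are redrawn (the redraw count is recorded).
#' Deterministic given the seed.
#'
#' @inheritParams fit_mediation
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return `mediation_result`: point estimates, per-effect CI and p,
#'   n_boot, seed, n_redrawn.
#' @export
bootstrap_mediation <- function(dosage, mediator, outcome, covariates = NULL,
                                n_boot = 1000, seed = 1L, conf = 0.95) {
  point <- fit_mediation(dosage, mediator, outcome, covariates)
  ok <- !is.na(dosage) & !is.na(mediator) & !is.na(outcome)
  if (!is.null(covariates)) ok <- ok & complete.cases(covariates)
  d <- dosage[ok]; m <- mediator[ok]; y <- outcome[ok]
  C <- if (!is.null(covariates)) as.matrix(covariates)[ok, , drop = FALSE] else NULL
  n <- length(d)
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    n_redrawn <- 0L
    repeat {
      degen <- apply(idx, 2, function(i) length(unique(d[i])) < 2)
      if (!any(degen)) break
      n_redrawn <- n_redrawn + sum(degen)
      idx[, degen] <- sample.int(n, n * sum(degen), replace = TRUE)
    }
    stats <- if (is.null(C)) {
      mediation_boot_block(d, m, y, idx)
    } else {
      t(apply(idx, 2, function(i) {
        f <- fit_mediation(d[i], m[i], y[i], C[i, , drop = FALSE])
        c(acme = f$acme, ade = f$ade, te = f$te)
      }))
    }
  })
  alpha <- 1 - conf
  summarize <- function(v, est) {
    ci <- unname(quantile(v, c(alpha / 2, 1 - alpha / 2), type = 7))
    p <- 2 * min(sum(v <= 0) + 1, sum(v >= 0) + 1) / (n_boot + 1)
    list(estimate = est, ci_low = ci[1], ci_high = ci[2],
      p_value = min(1, max(p, 2 / (n_boot + 1))))
  }
  structure(list(
    acme = summarize(stats[, "acme"], point$acme),
    ade = summarize(stats[, "ade"], point$ade),
    te = summarize(stats[, "te"], point$te),
    prop_mediated = point$prop_mediated,
    n_boot = n_boot, seed = seed, n_redrawn = n_redrawn
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  fmt <- function(nm, s) sprintf("  %-4s %8.4f  [%8.4f, %8.4f]  p = %.4g",
    nm, s$estimate, s$ci_low, s$ci_high, s$p_value)
  cat("mediation (", x$n_boot, " bootstrap resamples)\n", sep = "")
  cat(fmt("ACME", x$acme), "\n")
  cat(fmt("ADE", x$ade), "\n")
  cat(fmt("TE", x$te), "\n")
  invisible(x)
}

#' Mediation in both causal directions
#'
#' Runs the bootstrap analysis once with accessibility as the mediator
#' and expression as the outcome (forward) and once with the roles
#' reversed, reporting both rather than guessing the direction.
#'
#' @param dosage,accessibility,expression aligned numeric vectors.
#' @param covariates optional covariate matrix.
#' @param n_boot,seed,conf passed to [bootstrap_mediation()]; the reverse
#'   direction uses seed + 1.
#' @return list(forward = `mediation_result`, reverse = `mediation_result`).
#' @export
mediate_both_directions <- function(dosage, accessibility, expression,
                                    covariates = NULL, n_boot = 1000,
                                    seed = 1L, conf = 0.95) {
  list(
    forward = bootstrap_mediation(dosage, accessibility, expression,
      covariates, n_boot = n_boot, seed = seed, conf = conf),
    reverse = bootstrap_mediation(dosage, expression, accessibility,
      covariates, n_boot = n_boot, seed = seed + 1L, conf = conf)
  )
}
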