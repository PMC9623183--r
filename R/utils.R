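#' @keywords internal
"_PACKAGE"

#' @importFrom stats prcomp pchisq pt pnorm qnorm runif rnorm rexp cor median
#'   fisher.test wilcox.test p.adjust complete.cases sd var quantile setNames
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded helpers do not disturb
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## stable log(exp(a) - exp(b)), requires a >= b
logdiffexp <- function(a, b) {
  if (b > a) stop("logdiffexp requires a >= b")
  if (b == a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Odds ratio with Woolf-logit confidence interval
#'
#' Computes the cross-product odds ratio for a 2x2 table together with a
#' 95% Woolf (log-scale Wald) confidence interval and a two-sided Fisher
#' exact p-value. When any cell is zero, a Haldane-Anscombe correction of
#' 0.5 is added to every cell for the OR and CI (the p-value uses the raw
#' table). A zero-margin table is flagged degenerate.
#'
#' @param a,b,c,d cell counts: a = fg in, b = fg out, c = bg in, d = bg out.
#' @param conf confidence level (default 0.95).
#' @return list with `or`, `ci_low`, `ci_high`, `p_value`, `corrected`
#'   (logical: Haldane correction applied), `degenerate`.
#' @export
odds_ratio_woolf <- function(a, b, c, d, conf = 0.95) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) NA_real_ else fisher.test(tab)$p.value
  corrected <- any(tab == 0)
  if (corrected) tab <- tab + 0.5
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  se <- sqrt(sum(1 / tab))
  zq <- qnorm(1 - (1 - conf) / 2)
  list(
    or = or,
    ci_low = exp(log(or) - zq * se),
    ci_high = exp(log(or) + zq * se),
    p_value = p,
    corrected = corrected,
    degenerate = degenerate
  )
}

## internal: peak data.frame (chrom,start,end 0-based half-open) -> GRanges
peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}

## internal: stop with a message built from sprintf pieces
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
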