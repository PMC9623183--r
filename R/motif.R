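## Allele-specific motif disruption: PWM container, exact match p-values
## via dynamic programming over a discretized score distribution, best
## variant-overlapping hit per allele, the lg(p_weak) - lg(p_strong)
## statistic with gain/loss calls, and motif-caQTL association.

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Counts (or probabilities) are pseudocount-smoothed and converted to
#' per-column probabilities; scanning scores are log2 likelihood ratios
#' against the background.
#'
#' @param counts 4 x width numeric matrix, rows A, C, G, T (counts or
#'   probabilities).
#' @param motif_id motif identifier.
#' @param pseudocount added to each count (default 0.01).
#' @param background base composition, sums to 1 (default uniform).
#' @return `pwm` object: motif_id, width, probabilities, llr (log2
#'   odds), counts, pseudocount, background.
#' @export
pwm <- function(counts, motif_id = "motif", pseudocount = 0.01,
                background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) abort("PWM needs 4 rows (A, C, G, T)")
  if (abs(sum(background) - 1) > 1e-6) abort("background must sum to 1")
  rownames(counts) <- BASES
  sm <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  llr <- log2(sm / background)
  structure(list(
    motif_id = motif_id, width = ncol(counts), probabilities = sm,
    llr = llr, counts = counts, pseudocount = pseudocount,
    background = background,
    cache = new.env(parent = emptyenv())
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s: width %d, consensus %s\n", x$motif_id, x$width,
    paste(BASES[apply(x$probabilities, 2, which.max)], collapse = "")))
  invisible(x)
}

## reverse-complement of a pwm: reverse columns, swap A<->T, C<->G
pwm_revcomp <- function(x) {
  rc <- x$llr[c("T", "G", "C", "A"), rev(seq_len(x$width)), drop = FALSE]
  rownames(rc) <- BASES
  rc
}

## score distribution support: DP over integer-discretized column scores.
## Returns list(base, granularity, probs) where probs[k+1] = P(int sum = k).
pwm_score_distribution <- function(x) {
  if (!is.null(x$cache$dist)) return(x$cache$dist)
  llr <- x$llr
  col_min <- apply(llr, 2, min)
  col_max <- apply(llr, 2, max)
  rng <- sum(col_max - col_min)
  ## lattice resolution: 1/20000 of the mean per-column score range, so
  ## accumulated rounding error stays well below 1e-3 in p-value mass
  g <- if (rng > 0) rng / (20000 * x$width) else 1
  int_scores <- round(sweep(llr, 2, col_min) / g)
  max_total <- sum(apply(int_scores, 2, max))
  probs <- c(1, numeric(max_total))
  bg <- x$background
  for (j in seq_len(x$width)) {
    nxt <- numeric(length(probs))
    for (bidx in 1:4) {
      s <- int_scores[bidx, j]
      nxt[(1 + s):(length(probs))] <- nxt[(1 + s):(length(probs))] +
        bg[bidx] * probs[1:(length(probs) - s)]
    }
    probs <- nxt
  }
  x$cache$dist <- list(base = sum(col_min), granularity = g, probs = probs)
  x$cache$dist
}

#' Exact PWM match p-value
#'
#' Probability that a random background-distributed sequence of the
#' motif's width scores at least `score`, computed by dynamic programming
#' over a finely discretized score distribution (agrees with exhaustive
#' enumeration to better than 1e-3 for enumerable widths).
#'
#' @param x a [pwm()].
#' @param score log2 likelihood-ratio match score.
#' @return p-value in [0, 1]; scores at or below the minimum achievable
#'   give 1.
#' @export
pwm_match_pvalue <- function(x, score) {
  dist <- pwm_score_distribution(x)
  ## half-lattice slack per column so words scoring exactly `score` are
  ## never dropped by rounding (ties at the threshold count as matches)
  k <- ceiling((score - dist$base) / dist$granularity - x$width / 2 - 1e-9)
  if (k <= 0) return(1)
  if (k > length(dist$probs) - 1) return(0)
  sum(dist$probs[(k + 1):length(dist$probs)])
}

## score every window of seq_int (integer-coded 1..4) against an llr
## matrix; returns vector over window starts
scan_llr <- function(seq_int, llr) {
  w <- ncol(llr)
  n <- length(seq_int)
  if (n < w) return(numeric(0))
  starts <- seq_len(n - w + 1)
  vapply(starts, function(s) {
    idx <- seq_int[s:(s + w - 1)]
    if (anyNA(idx)) return(NA_real_)
    sum(llr[cbind(idx, seq_len(w))])
  }, 0.0)
}

#' Best motif hit overlapping the variant position
#'
#' Scans every window (both strands by default) whose span covers
#' `variant_pos` and returns the hit with the smallest match p-value
#' (equivalently, the largest score). Windows containing N are skipped.
#'
#' @param sequence character string over A/C/G/T/N, length 2 * flank + 1
#'   (61 at the default flank of 30).
#' @param x a [pwm()].
#' @param variant_pos 1-based variant position within the sequence
#'   (default: center).
#' @param both_strands scan the reverse strand too (default TRUE).
#' @param flank expected flank size; the sequence must have length
#'   2 * flank + 1.
#' @return list(score, p, strand, offset) where offset is the 1-based
#'   window start on the given sequence, or NULL when no window covers
#'   the variant.
#' @export
best_overlapping_hit <- function(sequence, x, variant_pos = NULL,
                                 both_strands = TRUE, flank = 30) {
  len <- nchar(sequence)
  if (len != 2 * flank + 1) {
    abort("sequence length %d != 2 * %d + 1", len, flank)
  }
  if (is.null(variant_pos)) variant_pos <- flank + 1L
  seq_int <- match(strsplit(toupper(sequence), "")[[1]], BASES)
  w <- x$width
  if (w > len) return(NULL)
  starts <- seq_len(len - w + 1)
  covers <- starts <= variant_pos & variant_pos <= starts + w - 1
  if (!any(covers)) return(NULL)
  sc_fwd <- scan_llr(seq_int, x$llr)[covers]
  cand <- data.frame(score = sc_fwd, strand = "+", offset = starts[covers],
    stringsAsFactors = FALSE)
  if (both_strands) {
    sc_rev <- scan_llr(seq_int, pwm_revcomp(x))[covers]
    cand <- rbind(cand, data.frame(score = sc_rev, strand = "-",
      offset = starts[covers], stringsAsFactors = FALSE))
  }
  cand <- cand[!is.na(cand$score), , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  best <- cand[order(-cand$score, cand$strand, cand$offset)[1], ]
  list(score = best$score, p = pwm_match_pvalue(x, best$score),
    strand = best$strand, offset = best$offset)
}

#' Allele-specific motif disruption score
#'
#' Finds the best variant-overlapping hit for the reference and
#' alternative sequence, and quantifies the allelic difference as
#' log10(p_weak) - log10(p_strong) >= 0. Direction is "loss" when the
#' reference allele matches better, "gain" when the alternative does.
#' Returns NULL when neither allele has a hit below `p_threshold`.
#'
#' @param ref_seq,alt_seq allele sequences, equal length, differing at
#'   exactly `variant_pos`.
#' @param x a [pwm()].
#' @param variant_pos 1-based variant position (default: center).
#' @param p_threshold hit-calling threshold (default 1e-4).
#' @param both_strands scan both strands (default TRUE).
#' @param flank flank size (sequence length 2 * flank + 1).
#' @return one-row data.frame: motif_id, p_ref, p_alt, log_ratio,
#'   direction, hit_strand, hit_offset; or NULL.
#' @export
disruption_score <- function(ref_seq, alt_seq, x, variant_pos = NULL,
                             p_threshold = 1e-4, both_strands = TRUE,
                             flank = 30) {
  if (nchar(ref_seq) != nchar(alt_seq)) abort("allele sequences differ in length")
  diff <- which(strsplit(ref_seq, "")[[1]] != strsplit(alt_seq, "")[[1]])
  if (is.null(variant_pos)) variant_pos <- flank + 1L
  if (length(diff) > 1 || (length(diff) == 1 && diff != variant_pos)) {
    abort("sequences must differ only at the variant position (%d); they differ at: %s",
      variant_pos, paste(diff, collapse = ", "))
  }
  hr <- best_overlapping_hit(ref_seq, x, variant_pos, both_strands, flank)
  ha <- best_overlapping_hit(alt_seq, x, variant_pos, both_strands, flank)
  if (is.null(hr) || is.null(ha)) return(NULL)
  if (min(hr$p, ha$p) >= p_threshold) return(NULL)
  p_ref <- hr$p; p_alt <- ha$p
  ## p-value floor so the log ratio stays finite
  eps <- 1e-300
  log_ratio <- log10(max(p_ref, p_alt) + eps) - log10(min(p_ref, p_alt) + eps)
  loss <- p_ref <= p_alt
  best <- if (loss) hr else ha
  data.frame(
    motif_id = x$motif_id, p_ref = p_ref, p_alt = p_alt,
    log_ratio = log_ratio, direction = if (loss) "loss" else "gain",
    hit_strand = best$strand, hit_offset = best$offset,
    stringsAsFactors = FALSE
  )
}

#' Motif disruption vs caQTL status association
#'
#' Per motif, Fisher's exact test of the 2x2 table (SNP disrupts the
#' motif) x (SNP is a caQTL), with Haldane-corrected odds ratios.
#'
#' @param disruption_flags logical matrix SNPs x motifs (TRUE = motif
#'   disrupted at that SNP).
#' @param caqtl_flags logical vector per SNP.
#' @return data.frame motif_id, or, ci_low, ci_high, p_value, degenerate.
#' @export
motif_caqtl_association <- function(disruption_flags, caqtl_flags) {
  stopifnot(nrow(disruption_flags) == length(caqtl_flags))
  if (!any(caqtl_flags) || all(caqtl_flags)) {
    abort("need both caQTL and non-caQTL SNPs")
  }
  rows <- lapply(colnames(disruption_flags), function(m) {
    d <- disruption_flags[, m]
    orr <- odds_ratio_woolf(
      sum(d & caqtl_flags), sum(!d & caqtl_flags),
      sum(d & !caqtl_flags), sum(!d & !caqtl_flags)
    )
    data.frame(motif_id = m, or = orr$or, ci_low = orr$ci_low,
      ci_high = orr$ci_high, p_value = orr$p_value,
      degenerate = orr$degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Concordance between motif-preferred and more-accessible alleles
#'
#' For each disruption record joined to a caQTL effect size, the
#' stronger-match allele is ref for "loss" and alt for "gain"; the
#' higher-accessibility allele is alt when beta > 0 (dosage counts alt
#' alleles) and ref otherwise. Reports, per motif, the fraction of
#' records where the two agree.
#'
#' @param disruptions data.frame with motif_id, direction and a
#'   variant/peak join key matching `qtl_betas`.
#' @param qtl_betas data.frame with the same join key and a beta column.
#' @param by join key column(s) (default "variant_id").
#' @return data.frame motif_id, n, fraction_concordant.
#' @export
accessibility_concordance <- function(disruptions, qtl_betas,
                                      by = "variant_id") {
  joined <- merge(disruptions, qtl_betas[, c(by, "beta")], by = by)
  joined <- joined[!is.na(joined$beta) & joined$beta != 0, , drop = FALSE]
  if (nrow(joined) == 0) {
    return(data.frame(motif_id = character(0), n = integer(0),
      fraction_concordant = numeric(0)))
  }
  stronger_is_alt <- joined$direction == "gain"
  higher_is_alt <- joined$beta > 0
  joined$concordant <- stronger_is_alt == higher_is_alt
  agg <- stats::aggregate(concordant ~ motif_id, data = joined,
    FUN = function(v) c(n = length(v), frac = mean(v)))
  data.frame(
    motif_id = agg$motif_id,
    n = as.integer(agg$concordant[, "n"]),
    fraction_concordant = as.numeric(agg$concordant[, "frac"]),
    stringsAsFactors = FALSE
  )
}
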