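## Fixed-width peak construction: summit extension, iterative overlap
## removal, score-per-million normalization, cross-sample consensus and
## the consensus-level filters. Coordinates are BED-style 0-based
## half-open throughout; summits are absolute 0-based positions.

#' Extend peak summits to fixed-width intervals
#'
#' Each summit becomes the interval [summit - flank, summit + flank + 1),
#' i.e. width 2 * flank + 1 (501 bp at the default). Peaks that would
#' extend past either end of their chromosome are removed (with a message
#' listing how many).
#'
#' @param summits data.frame with chrom, summit (0-based position), score.
#' @param flank extension on each side in bp (default 250).
#' @param chrom_sizes optional named vector of chromosome lengths; when
#'   given, peaks running past the end are removed.
#' @return peak data.frame (chrom, start, end, name, score, summit).
#' @export
extend_summits <- function(summits, flank = 250, chrom_sizes = NULL) {
  stopifnot(all(c("chrom", "summit", "score") %in% names(summits)))
  start <- summits$summit - flank
  end <- summits$summit + flank + 1L
  keep <- start >= 0
  if (!is.null(chrom_sizes)) {
    len <- chrom_sizes[as.character(summits$chrom)]
    keep <- keep & !is.na(len) & end <= len
  }
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(n_removed, " peak(s) extending beyond chromosome bounds removed")
  }
  out <- data.frame(
    chrom = as.character(summits$chrom)[keep],
    start = as.integer(start[keep]), end = as.integer(end[keep]),
    name = if ("name" %in% names(summits)) summits$name[keep] else
      sprintf("peak_%d", which(keep)),
    score = summits$score[keep],
    summit = as.integer(summits$summit[keep]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Iterative overlap removal
#'
#' Greedy selection by descending score: keep the most significant peak,
#' discard every peak overlapping it (>= 1 shared bp, same chromosome),
#' and repeat on the remainder. Equivalently, scanning peaks in descending
#' score order, a peak is kept iff it overlaps no previously kept peak.
#' Score ties are broken by (chrom, start) ascending for determinism.
#'
#' @param peaks peak data.frame.
#' @return the retained, pairwise non-overlapping subset, in input row
#'   order restricted to survivors.
#' @export
iterative_removal <- function(peaks) {
  n <- nrow(peaks)
  if (n <= 1) return(peaks)
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  gr <- peaks_to_granges(peaks)
  hits <- GenomicRanges::findOverlaps(gr, gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  keep_self <- qh != sh
  adj <- split(sh[keep_self], qh[keep_self])
  kept <- logical(n)
  alive <- rep(TRUE, n)
  for (i in ord) {
    if (!alive[i]) next
    kept[i] <- TRUE
    nb <- adj[[as.character(i)]]
    if (!is.null(nb)) alive[nb] <- FALSE
  }
  out <- peaks[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score-per-million normalization
#'
#' Divides each score by the sample's total score and scales to one
#' million, making peak significance comparable across samples with
#' different depth.
#'
#' @param scores nonnegative per-peak scores for one sample.
#' @return SPM values summing to 1e6.
#' @export
spm_normalize <- function(scores) {
  if (any(scores < 0)) abort("scores must be nonnegative")
  total <- sum(scores)
  if (total <= 0) abort("zero total score: SPM undefined")
  scores / total * 1e6
}

#' Build a cross-sample consensus accessibility matrix
#'
#' Pools every sample's (SPM-scored) peaks, applies [iterative_removal()]
#' to the pool, and quantifies each consensus peak in each sample as the
#' SPM of the sample's best-overlapping own peak (largest overlap, ties to
#' the higher SPM), 0 when the sample has no overlapping peak.
#'
#' @param per_sample_peaks named list: sample id -> peak data.frame with
#'   SPM in the score column (use [spm_normalize()] upstream).
#' @return `accessibility_matrix`: `peaks`, `values` (peaks x samples),
#'   `n_samples_observed`.
#' @export
build_consensus <- function(per_sample_peaks) {
  samples <- names(per_sample_peaks)
  if (is.null(samples) || any(!nzchar(samples))) {
    abort("per_sample_peaks must be a named list keyed by sample id")
  }
  pool <- do.call(rbind, lapply(per_sample_peaks, function(p) p))
  if (is.null(pool) || nrow(pool) == 0) {
    return(structure(list(
      peaks = data.frame(chrom = character(0), start = integer(0),
        end = integer(0), name = character(0), score = numeric(0),
        summit = integer(0)),
      values = matrix(0, 0, length(samples), dimnames = list(NULL, samples)),
      n_samples_observed = integer(0)
    ), class = "accessibility_matrix"))
  }
  rownames(pool) <- NULL
  consensus <- iterative_removal(pool)
  ## stable genomic order and fresh names
  consensus <- consensus[order(consensus$chrom, consensus$start), , drop = FALSE]
  consensus$name <- sprintf("consensus_%d", seq_len(nrow(consensus)))
  rownames(consensus) <- NULL
  gr_cons <- peaks_to_granges(consensus)
  values <- matrix(0, nrow(consensus), length(samples),
    dimnames = list(consensus$name, samples))
  for (s in samples) {
    ps <- per_sample_peaks[[s]]
    if (is.null(ps) || nrow(ps) == 0) next
    gr_s <- peaks_to_granges(ps)
    hits <- GenomicRanges::findOverlaps(gr_cons, gr_s)
    if (length(hits) == 0) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr_cons)[qh], IRanges::ranges(gr_s)[sh]))
    spm <- ps$score[sh]
    ## best overlap per consensus peak: max width, tie -> max SPM
    o <- order(qh, -ov, -spm)
    first <- !duplicated(qh[o])
    values[qh[o][first], s] <- spm[o][first]
  }
  structure(list(
    peaks = consensus, values = values,
    n_samples_observed = as.integer(rowSums(values > 0))
  ), class = "accessibility_matrix")
}

#' @export
print.accessibility_matrix <- function(x, ...) {
  cat(sprintf("accessibility_matrix: %d peaks x %d samples\n",
    nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Filter a consensus accessibility matrix
#'
#' Keeps peaks observed in at least `min_samples` samples, with maximum
#' SPM across samples at least `min_spm`, on autosomes (when
#' `autosomes_only`), and not overlapping any blacklist interval.
#'
#' @param acc an `accessibility_matrix`.
#' @param min_samples minimum number of samples with an overlapping call
#'   (inclusive; default 2).
#' @param min_spm minimum of the per-peak maximum SPM (inclusive).
#' @param autosomes_only restrict to chr1..chr22 / 1..22.
#' @param blacklist optional exclusion intervals (data.frame chrom, start,
#'   end) such as the ENCODE DAC list; >= 1 bp overlap removes the peak.
#' @return filtered `accessibility_matrix`.
#' @export
filter_consensus <- function(acc, min_samples = 2, min_spm = 5,
                             autosomes_only = TRUE, blacklist = NULL) {
  keep <- acc$n_samples_observed >= min_samples
  keep <- keep & apply(acc$values, 1, max) >= min_spm
  if (autosomes_only) {
    autosomes <- c(paste0("chr", 1:22), as.character(1:22))
    keep <- keep & acc$peaks$chrom %in% autosomes
  }
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    gr_b <- GenomicRanges::GRanges(blacklist$chrom,
      IRanges::IRanges(blacklist$start + 1L, blacklist$end))
    hit <- GenomicRanges::countOverlaps(peaks_to_granges(acc$peaks), gr_b) > 0
    keep <- keep & !hit
  }
  structure(list(
    peaks = {
      p <- acc$peaks[keep, , drop = FALSE]; rownames(p) <- NULL; p
    },
    values = acc$values[keep, , drop = FALSE],
    n_samples_observed = acc$n_samples_observed[keep]
  ), class = "accessibility_matrix")
}
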