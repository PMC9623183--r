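## Chromatin-state annotation: merged state tracks, peak-to-state
## assignment with the quiescent 100% rule, Fisher enrichment against
## shuffled backgrounds, and the TSS-peak / expression association.

#' Default raw-to-merged chromatin state map (18-state vocabulary)
#'
#' Promoter-flavored states collapse to "promoter", transcription to
#' "transcribed", enhancer-flavored to "enhancer", polycomb-repressed to
#' "polycomb", ZNF/repeats to "znf_repeats", heterochromatin and
#' quiescent to their own labels.
#'
#' @return named character vector raw label -> merged label.
#' @export
default_state_merge_map <- function() {
  c(
    "1_TssA" = "promoter", "2_TssFlnk" = "promoter",
    "3_TssFlnkU" = "promoter", "4_TssFlnkD" = "promoter",
    "14_TssBiv" = "promoter",
    "5_Tx" = "transcribed", "6_TxWk" = "transcribed",
    "7_EnhG1" = "enhancer", "8_EnhG2" = "enhancer",
    "9_EnhA1" = "enhancer", "10_EnhA2" = "enhancer",
    "11_EnhWk" = "enhancer", "15_EnhBiv" = "enhancer",
    "16_ReprPC" = "polycomb", "17_ReprPCWk" = "polycomb",
    "12_ZNF/Rpts" = "znf_repeats",
    "13_Het" = "heterochromatin",
    "18_Quies" = "quiescent"
  )
}

## fixed priority for coverage ties; quiescent last by construction
state_priority <- c("promoter", "enhancer", "transcribed", "polycomb",
  "znf_repeats", "heterochromatin", "quiescent")

#' Construct a chromatin-state track
#'
#' @param intervals data.frame chrom, start, end (0-based half-open),
#'   label (raw state label).
#' @param merge_map named vector mapping every raw label to a merged
#'   state; defaults to [default_state_merge_map()].
#' @return `state_track` object with merged labels attached.
#' @export
state_track <- function(intervals, merge_map = default_state_merge_map()) {
  stopifnot(all(c("chrom", "start", "end", "label") %in% names(intervals)))
  unmapped <- setdiff(unique(intervals$label), names(merge_map))
  if (length(unmapped) > 0) {
    abort("raw state label(s) not in merge map: %s",
      paste(head(unmapped, 5), collapse = ", "))
  }
  ## per-chrom non-overlap check
  by_chrom <- split(intervals, intervals$chrom)
  for (iv in by_chrom) {
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)])) {
      abort("state intervals overlap on %s", iv$chrom[1])
    }
  }
  intervals$merged <- unname(merge_map[intervals$label])
  structure(list(intervals = intervals, merge_map = merge_map),
    class = "state_track")
}

#' Assign peaks to merged chromatin states
#'
#' Each peak takes the merged state with the highest bp coverage, except
#' quiescent: quiescent is assigned only when it covers 100% of the peak;
#' if quiescent has the top coverage but less than 100%, the next-highest
#' covered state is used. Peaks on chromosomes absent from the track (or
#' covered by no interval) are "unannotated". Coverage ties are broken by
#' a fixed priority (promoter > enhancer > transcribed > polycomb >
#' znf_repeats > heterochromatin).
#'
#' @param peaks peak data.frame.
#' @param track a [state_track()].
#' @return character vector of merged state labels, one per peak.
#' @export
assign_state <- function(peaks, track) {
  stopifnot(inherits(track, "state_track"))
  iv <- track$intervals
  gr_p <- peaks_to_granges(peaks)
  gr_s <- GenomicRanges::GRanges(iv$chrom,
    IRanges::IRanges(iv$start + 1L, iv$end))
  hits <- GenomicRanges::findOverlaps(gr_p, gr_s)
  out <- rep("unannotated", nrow(peaks))
  if (length(hits) == 0) return(out)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_p)[qh], IRanges::ranges(gr_s)[sh]))
  state <- iv$merged[sh]
  width <- peaks$end - peaks$start
  cov_df <- data.frame(peak = qh, state = state, ov = ov)
  agg <- stats::aggregate(ov ~ peak + state, data = cov_df, FUN = sum)
  for (p in unique(agg$peak)) {
    rows <- agg[agg$peak == p, ]
    rows$prio <- match(rows$state, state_priority)
    rows <- rows[order(-rows$ov, rows$prio), ]
    top <- rows$state[1]
    if (top == "quiescent") {
      if (rows$ov[1] >= width[p]) {
        out[p] <- "quiescent"
      } else if (nrow(rows) > 1) {
        out[p] <- rows$state[2]
      } else {
        ## quiescent is the only overlapping state but coverage < 100%:
        ## no non-quiescent evidence, leave unannotated
        out[p] <- "unannotated"
      }
    } else {
      out[p] <- top
    }
  }
  out
}

#' Chromatin-state enrichment of a foreground set against a background
#'
#' Assigns both sets to merged states and, per state, tests the 2x2 table
#' (in state vs not) x (foreground vs background) with Fisher's exact test
#' and a Woolf-logit 95% CI (Haldane 0.5 on zero cells).
#'
#' @param foreground,background peak data.frames (or any interval
#'   data.frame with chrom/start/end).
#' @param track a [state_track()].
#' @return data.frame, one row per merged state: category, odds_ratio,
#'   ci_low, ci_high, p_value, fg_in, fg_out, bg_in, bg_out.
#' @export
state_enrichment <- function(foreground, background, track) {
  if (nrow(foreground) == 0 || nrow(background) == 0) {
    abort("foreground and background must be nonempty")
  }
  fg_states <- assign_state(foreground, track)
  bg_states <- assign_state(background, track)
  cats <- intersect(state_priority, unique(c(fg_states, bg_states)))
  rows <- lapply(cats, function(s) {
    a <- sum(fg_states == s); b <- sum(fg_states != s)
    c_ <- sum(bg_states == s); d <- sum(bg_states != s)
    orr <- odds_ratio_woolf(a, b, c_, d)
    data.frame(
      category = s, odds_ratio = orr$or, ci_low = orr$ci_low,
      ci_high = orr$ci_high, p_value = orr$p_value,
      fg_in = a, fg_out = b, bg_in = c_, bg_out = d,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Shuffle intervals to build a random background
#'
#' Relocates each interval uniformly at random on its own chromosome,
#' preserving its width, rejecting placements that overlap an already
#' placed output interval. Deterministic given the seed.
#'
#' @param intervals data.frame chrom, start, end.
#' @param genome_sizes named vector of chromosome lengths.
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap per interval.
#' @return relocated intervals (chrom, start, end), same widths.
#' @export
shuffle_background <- function(intervals, genome_sizes, seed,
                               max_tries = 1000) {
  with_seed(seed, {
    n <- nrow(intervals)
    out_start <- integer(n)
    widths <- intervals$end - intervals$start
    placed <- vector("list", length(genome_sizes))
    names(placed) <- names(genome_sizes)
    for (i in seq_len(n)) {
      chrom <- as.character(intervals$chrom[i])
      size <- if (chrom %in% names(genome_sizes)) genome_sizes[[chrom]] else NULL
      if (is.null(size) || size < widths[i]) {
        abort("chromosome %s too small for a %d bp interval", chrom, widths[i])
      }
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        s <- sample.int(size - widths[i] + 1, 1) - 1L
        e <- s + widths[i]
        prev <- placed[[chrom]]
        if (is.null(prev) ||
            !any(s < prev[, 2] & e > prev[, 1])) {
          ok <- TRUE
          break
        }
      }
      if (!ok) abort("could not place interval %d without overlap", i)
      out_start[i] <- s
      placed[[chrom]] <- rbind(placed[[chrom]], c(s, e))
    }
    data.frame(
      chrom = intervals$chrom, start = out_start,
      end = out_start + widths, stringsAsFactors = FALSE
    )
  })
}

#' TSS-peak presence vs expression association
#'
#' Flags each gene as expressed (median TPM > 1) and as TSS-peaked (some
#' peak interval contains the TSS base), tests the 2x2 with Fisher's
#' exact test plus Woolf CI, and compares TPM between expressed genes
#' with and without a TSS peak by Wilcoxon rank-sum. With complete
#' separation the Haldane-corrected OR is reported and `or_infinite` set.
#'
#' @param expression genes x samples TPM matrix.
#' @param tss data.frame gene, chrom, pos (1-based TSS coordinate).
#' @param peaks peak data.frame.
#' @return list: `fisher` (or, ci, p, table, or_infinite), `expression_test`
#'   (wilcoxon p, group medians, n per group; NA-flagged when a stratum is
#'   empty).
#' @export
tss_peak_expression_association <- function(expression, tss, peaks) {
  genes <- intersect(rownames(expression), tss$gene)
  if (length(genes) == 0) abort("no genes shared between expression and TSS table")
  tss <- tss[match(genes, tss$gene), ]
  med <- apply(expression[genes, , drop = FALSE], 1, median)
  expressed <- med > 1
  gr_tss <- GenomicRanges::GRanges(tss$chrom, IRanges::IRanges(tss$pos, tss$pos))
  has_peak <- GenomicRanges::countOverlaps(gr_tss, peaks_to_granges(peaks)) > 0
  a <- sum(expressed & has_peak); b <- sum(expressed & !has_peak)
  c_ <- sum(!expressed & has_peak); d <- sum(!expressed & !has_peak)
  orr <- odds_ratio_woolf(a, b, c_, d)
  raw_or_infinite <- (b == 0 || c_ == 0) && a > 0 && d > 0
  expr_test <- list(p_value = NA_real_, median_with = NA_real_,
    median_without = NA_real_, n_with = sum(expressed & has_peak),
    n_without = sum(expressed & !has_peak), defined = FALSE)
  if (expr_test$n_with > 0 && expr_test$n_without > 0) {
    with_tpm <- med[expressed & has_peak]
    without_tpm <- med[expressed & !has_peak]
    wt <- suppressWarnings(wilcox.test(with_tpm, without_tpm))
    expr_test <- list(
      p_value = wt$p.value, median_with = median(with_tpm),
      median_without = median(without_tpm),
      n_with = length(with_tpm), n_without = length(without_tpm),
      defined = TRUE
    )
  }
  list(
    fisher = list(
      or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
      p_value = orr$p_value, or_infinite = raw_or_infinite,
      table = matrix(c(a, b, c_, d), 2, byrow = TRUE,
        dimnames = list(c("expressed", "not_expressed"),
          c("tss_peak", "no_tss_peak")))
    ),
    expression_test = expr_test
  )
}
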