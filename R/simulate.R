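## Synthetic-data generators with the statistical structure the downstream
## stages assume: HWE genotypes with LD-block structure, accessibility with
## planted linear genotype effects, expression with a genotype ->
## accessibility -> expression mediation chain, exponential survival with
## genotype-dependent hazards, chromatin-state tracks, and motif loci with
## a variant that breaks the consensus.

#' Simulation configuration
#'
#' All generators are driven by one validated configuration so that a run
#' is reproducible from (config, seed) alone.
#'
#' @param n_samples number of donors.
#' @param n_variants number of variants on the synthetic chromosome.
#' @param maf_range minor-allele-frequency range, both ends in (0, 0.5].
#' @param ld_block_size variants per LD block.
#' @param ld_rho latent Gaussian correlation between adjacent variants
#'   within a block, in [0, 1).
#' @param n_peaks number of accessibility peaks.
#' @param planted_effects data.frame (variant_id, peak_id, beta): linear
#'   accessibility effect per alt allele, SPM-scale units.
#' @param noise_sd residual SD for accessibility and expression.
#' @param mediation_specs data.frame (variant_id, peak_id, gene_id, a, b,
#'   c_direct): genotype->mediator slope a, mediator->outcome slope b,
#'   direct slope c_direct.
#' @param survival_specs data.frame (variant_id, log_hazard): per-allele
#'   log hazard ratio.
#' @param censor_rate expected fraction of donors censored, in [0, 1].
#' @param n_null_genes extra genes with no genotype or accessibility input.
#' @param chrom chromosome name for all coordinates.
#' @param chrom_length synthetic chromosome length in bp.
#' @param baseline_hazard exponential baseline hazard per day.
#' @param seed integer seed; every generator derives its stream from it.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 100, n_variants = 200,
                       maf_range = c(0.05, 0.5), ld_block_size = 10,
                       ld_rho = 0.0, n_peaks = 50,
                       planted_effects = NULL, noise_sd = 1,
                       mediation_specs = NULL, survival_specs = NULL,
                       censor_rate = 0.3, n_null_genes = 0,
                       chrom = "chr1", chrom_length = 10e6,
                       baseline_hazard = 1 / 1000, seed = 1L) {
  cfg <- list(
    n_samples = n_samples, n_variants = n_variants, maf_range = maf_range,
    ld_block_size = ld_block_size, ld_rho = ld_rho, n_peaks = n_peaks,
    planted_effects = planted_effects, noise_sd = noise_sd,
    mediation_specs = mediation_specs, survival_specs = survival_specs,
    censor_rate = censor_rate, n_null_genes = n_null_genes,
    chrom = chrom, chrom_length = chrom_length,
    baseline_hazard = baseline_hazard, seed = as.integer(seed)
  )
  if (n_samples < 2) abort("invalid config: n_samples must be >= 2")
  if (n_variants < 1) abort("invalid config: n_variants must be >= 1")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("invalid config: maf_range must be within (0, 0.5]")
  }
  if (ld_rho < 0 || ld_rho >= 1) abort("invalid config: ld_rho must be in [0, 1)")
  if (ld_block_size < 1) abort("invalid config: ld_block_size must be >= 1")
  if (noise_sd <= 0) abort("invalid config: noise_sd must be > 0")
  if (censor_rate < 0 || censor_rate > 1) {
    abort("invalid config: censor_rate must be in [0, 1]")
  }
  vid <- function(i) sprintf("var_%04d", i)
  pid <- function(i) sprintf("peak_%04d", i)
  check_refs <- function(df, col, valid, what) {
    bad <- setdiff(df[[col]], valid)
    if (length(bad) > 0) {
      abort("unknown %s referenced in config: %s", what,
        paste(head(bad, 3), collapse = ", "))
    }
  }
  vids <- vid(seq_len(n_variants))
  pids <- pid(seq_len(n_peaks))
  if (!is.null(planted_effects)) {
    check_refs(planted_effects, "variant_id", vids, "variant_id")
    check_refs(planted_effects, "peak_id", pids, "peak_id")
  }
  if (!is.null(mediation_specs)) {
    check_refs(mediation_specs, "variant_id", vids, "variant_id")
    check_refs(mediation_specs, "peak_id", pids, "peak_id")
  }
  if (!is.null(survival_specs)) {
    check_refs(survival_specs, "variant_id", vids, "variant_id")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate genotypes under HWE with LD blocks
#'
#' Per-variant MAFs are drawn uniformly from `maf_range`. Within each block
#' of `ld_block_size` consecutive variants, a latent AR(1) Gaussian with
#' parameter `ld_rho` is thresholded at the Hardy-Weinberg genotype
#' quantiles of each variant's MAF (a Gaussian-copula construction), so
#' marginals are exactly HWE while adjacent variants are correlated.
#' Variant positions are sorted uniform draws along the chromosome.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    m <- config$n_variants
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    pos <- sort(sample.int(config$chrom_length - 2, m))
    ## latent AR(1) per block
    z <- matrix(NA_real_, n, m)
    rho <- config$ld_rho
    for (j in seq_len(m)) {
      new_block <- (j - 1) %% config$ld_block_size == 0
      e <- rnorm(n)
      z[, j] <- if (new_block || rho == 0) e else rho * z[, j - 1] + sqrt(1 - rho^2) * e
    }
    u <- pnorm(z)
    dos <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      p <- maf[j] # alt allele frequency (alt is the minor allele)
      q0 <- (1 - p)^2
      q1 <- q0 + 2 * p * (1 - p)
      dos[, j] <- ifelse(u[, j] < q0, 0L, ifelse(u[, j] < q1, 1L, 2L))
    }
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")
    variants <- data.frame(
      id = sprintf("var_%04d", seq_len(m)),
      chrom = config$chrom, pos = pos, ref = ref, alt = unname(alt),
      info_score = runif(m, 0.8, 1.0), stringsAsFactors = FALSE
    )
    genotype_matrix(dos, variants,
      samples = sprintf("donor_%03d", seq_len(n)))
  })
}

#' Simulate an accessibility matrix with planted genotype effects
#'
#' Each peak's value is `baseline + beta * dosage + N(0, noise_sd)` where
#' beta is nonzero only for planted (variant, peak) pairs. Baselines are
#' log-normal (SPM-like positive scale). Peaks occupy non-overlapping
#' 501-bp intervals on a 1-kb grid; a planted peak is placed on the grid
#' slot nearest its causal variant so the pair is well inside the cis
#' window.
#'
#' @param genotypes a [genotype_matrix()] from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return list with `peaks` (peak data.frame) and `values`
#'   (peaks x samples matrix), class `accessibility_matrix`.
#' @export
simulate_accessibility <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    n <- config$n_samples
    k <- config$n_peaks
    slots <- seq(0, config$chrom_length - 1001, by = 1000)
    if (length(slots) < k) abort("chromosome too short for %d peaks", k)
    chosen <- sort(sample(slots, k))
    ## pin planted peaks next to their causal variants (nearest free slot)
    pe <- config$planted_effects
    if (!is.null(pe) && nrow(pe) > 0) {
      for (r in seq_len(nrow(pe))) {
        vpos <- genotypes$variants$pos[genotypes$variants$id == pe$variant_id[r]]
        if (length(vpos) == 0) abort("planted effect references unknown variant %s", pe$variant_id[r])
        pk <- as.integer(sub("peak_", "", pe$peak_id[r]))
        candidates <- setdiff(slots, chosen[-pk])
        chosen[pk] <- candidates[which.min(abs(candidates - vpos))]
      }
    }
    start <- chosen + 200L
    peaks <- data.frame(
      chrom = config$chrom, start = start, end = start + 501L,
      name = sprintf("peak_%04d", seq_len(k)),
      score = NA_real_, summit = start + 250L, stringsAsFactors = FALSE
    )
    baseline <- 5 + exp(rnorm(k, log(20), 0.5))
    values <- matrix(rnorm(k * n, 0, config$noise_sd), k, n)
    values <- values + baseline
    if (!is.null(pe) && nrow(pe) > 0) {
      for (r in seq_len(nrow(pe))) {
        i <- match(pe$peak_id[r], peaks$name)
        dos <- genotypes$dosages[, pe$variant_id[r]]
        values[i, ] <- values[i, ] + pe$beta[r] * dos
      }
    }
    values[values < 0] <- 0
    dimnames(values) <- list(peaks$name, genotypes$samples)
    structure(list(peaks = peaks, values = values,
      n_samples_observed = rep(ncol(values), k)),
      class = "accessibility_matrix")
  })
}

#' Simulate expression with a mediation structure
#'
#' For each mediation spec, `gene = c_direct * dosage + b * peak +
#' N(0, noise_sd)`; because the peak itself carries `a * dosage`, the total
#' genotype effect is `a * b + c_direct` by construction. Null genes are
#' pure noise around a log-normal baseline. Genes are assigned TSS
#' positions near their mediating peak (null genes: random positions).
#'
#' @param genotypes,accessibility,config outputs of the upstream
#'   generators plus the shared [sim_config()].
#' @return list with `values` (genes x samples), `tss` (gene, chrom, pos).
#' @export
simulate_expression <- function(genotypes, accessibility, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    specs <- config$mediation_specs
    n <- config$n_samples
    gene_ids <- character(0)
    rows <- list()
    tss <- list()
    if (!is.null(specs) && nrow(specs) > 0) {
      for (r in seq_len(nrow(specs))) {
        dos <- genotypes$dosages[, specs$variant_id[r]]
        peak <- accessibility$values[specs$peak_id[r], ]
        g <- specs$c_direct[r] * dos + specs$b[r] * peak +
          rnorm(n, 0, config$noise_sd)
        rows[[specs$gene_id[r]]] <- g
        pk <- accessibility$peaks[accessibility$peaks$name == specs$peak_id[r], ]
        tss[[specs$gene_id[r]]] <- data.frame(
          gene = specs$gene_id[r], chrom = pk$chrom,
          pos = pk$start + 5000L, stringsAsFactors = FALSE
        )
      }
    }
    if (config$n_null_genes > 0) {
      for (i in seq_len(config$n_null_genes)) {
        gid <- sprintf("null_gene_%03d", i)
        rows[[gid]] <- exp(rnorm(1, log(10), 0.5)) + rnorm(n, 0, config$noise_sd)
        tss[[gid]] <- data.frame(
          gene = gid, chrom = config$chrom,
          pos = sample.int(config$chrom_length - 1, 1), stringsAsFactors = FALSE
        )
      }
    }
    if (length(rows) == 0) {
      return(list(values = matrix(0, 0, n,
        dimnames = list(NULL, genotypes$samples)),
        tss = data.frame(gene = character(0), chrom = character(0),
          pos = integer(0))))
    }
    values <- do.call(rbind, rows)
    dimnames(values) <- list(names(rows), genotypes$samples)
    list(values = values, tss = do.call(rbind, c(tss, list(make.row.names = FALSE))))
  })
}

#' Simulate exponential survival with genotype-dependent hazards
#'
#' Event times are exponential with hazard
#' `h0 * exp(sum_v log_hazard_v * dosage_v)`. Censoring is independent:
#' each donor is censored with probability `censor_rate`, at a uniform
#' fraction of the event time.
#'
#' @param genotypes a [genotype_matrix()].
#' @param config the shared [sim_config()].
#' @return data.frame (donor, time_days, event).
#' @export
simulate_survival <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 3L, {
    n <- config$n_samples
    loghaz <- rep(0, n)
    specs <- config$survival_specs
    if (!is.null(specs) && nrow(specs) > 0) {
      for (r in seq_len(nrow(specs))) {
        loghaz <- loghaz + specs$log_hazard[r] *
          genotypes$dosages[, specs$variant_id[r]]
      }
    }
    t_event <- rexp(n, rate = config$baseline_hazard * exp(loghaz))
    censored <- runif(n) < config$censor_rate
    time <- ifelse(censored, t_event * runif(n), t_event)
    time <- pmax(time, 1e-6)
    data.frame(
      donor = genotypes$samples, time_days = time,
      event = as.integer(!censored), stringsAsFactors = FALSE
    )
  })
}

#' Simulate a chromatin-state track
#'
#' Tiles the synthetic chromosome with intervals labeled by the 18-state
#' raw vocabulary (weighted toward quiescent, as real segmentations are),
#' non-overlapping and covering the chromosome.
#'
#' @param config a [sim_config()].
#' @param mean_interval mean interval length in bp.
#' @return a [state_track()].
#' @export
simulate_state_track <- function(config, mean_interval = 20000) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 4L, {
    labels <- names(default_state_merge_map())
    weights <- ifelse(default_state_merge_map() == "quiescent", 8,
      ifelse(default_state_merge_map() %in% c("promoter", "enhancer"), 2, 1))
    cuts <- sort(sample.int(config$chrom_length - 1,
      max(2, round(config$chrom_length / mean_interval))))
    bounds <- unique(c(0L, cuts, as.integer(config$chrom_length)))
    n_int <- length(bounds) - 1
    lab <- sample(labels, n_int, replace = TRUE, prob = weights)
    state_track(data.frame(
      chrom = config$chrom, start = bounds[-length(bounds)],
      end = bounds[-1], label = lab, stringsAsFactors = FALSE
    ))
  })
}

#' Simulate a motif locus with a consensus-breaking variant
#'
#' Builds an informative PWM of the requested width, embeds its consensus
#' in a random 61-mer so that the consensus spans the central variant
#' position, and produces an alternative allele that substitutes the
#' consensus base at that position with the PWM's least-preferred base.
#' Sequences are the variant plus 30 bp of flank on each side.
#'
#' @param pwm_width motif width, 4..20.
#' @param seed integer seed.
#' @param flank flank size (default 30; sequence length 2 * flank + 1).
#' @return list: `pwm`, `ref_sequence`, `alt_sequence`, `variant_pos`
#'   (1-based position of the variant within the sequences).
#' @export
simulate_motif_locus <- function(pwm_width, seed, flank = 30) {
  if (pwm_width < 4 || pwm_width > 20) abort("pwm_width must be in [4, 20]")
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    len <- 2L * flank + 1L
    variant_pos <- flank + 1L
    consensus_idx <- sample.int(4, pwm_width, replace = TRUE)
    probs <- matrix(0.04, 4, pwm_width, dimnames = list(bases, NULL))
    for (j in seq_len(pwm_width)) probs[consensus_idx[j], j] <- 0.88
    mot <- pwm(probs * 100, motif_id = sprintf("SYN_W%d_S%d", pwm_width, seed))
    seq_ref <- sample(bases, len, replace = TRUE)
    ## embed consensus covering the variant position
    start <- sample(seq(max(1, variant_pos - pwm_width + 1),
      min(variant_pos, len - pwm_width + 1)), 1)
    seq_ref[start:(start + pwm_width - 1)] <- bases[consensus_idx]
    offset_in_motif <- variant_pos - start + 1
    worst <- bases[which.min(mot$probabilities[, offset_in_motif])]
    seq_alt <- seq_ref
    seq_alt[variant_pos] <- worst
    list(
      pwm = mot,
      ref_sequence = paste(seq_ref, collapse = ""),
      alt_sequence = paste(seq_alt, collapse = ""),
      variant_pos = variant_pos
    )
  })
}

#' Derive per-sample peak calls from a simulated accessibility matrix
#'
#' Turns the peaks x samples value matrix into one peak list per sample
#' (score = that sample's value), the shape the consensus-building stage
#' consumes. Peaks with nonpositive score in a sample are treated as not
#' called there.
#'
#' @param accessibility output of [simulate_accessibility()].
#' @return named list: sample id -> peak data.frame.
#' @export
simulate_peak_calls <- function(accessibility) {
  samples <- colnames(accessibility$values)
  out <- lapply(samples, function(s) {
    sc <- accessibility$values[, s]
    called <- sc > 0
    df <- accessibility$peaks[called, , drop = FALSE]
    df$score <- sc[called]
    rownames(df) <- NULL
    df
  })
  names(out) <- samples
  out
}
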