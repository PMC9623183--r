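## End-to-end orchestration: a validated config drives the stages in
## dependency order (qc -> peaks -> annotation -> mapping -> eqtl ->
## coloc -> mediation -> motif -> gwas -> survival), each stage writing a
## TSV plus a JSON sidecar recording parameters, counts and the seed.
## Identical configs reproduce byte-identical outputs.

#' Pipeline configuration
#'
#' @param out_dir output directory (created if absent).
#' @param sim a [sim_config()] describing the synthetic cohort.
#' @param stages stages to run, in dependency order; default all.
#' @param cis_window cis window in bp.
#' @param fdr_threshold caQTL/eQTL significance threshold on BH FDR.
#' @param min_samples,min_spm consensus peak filters.
#' @param coloc_priors list(p1, p2, p12).
#' @param prior_sd colocalization effect-size prior SD.
#' @param pp4_threshold colocalized-call threshold.
#' @param n_boot mediation bootstrap resamples.
#' @param ld_threshold GWAS-overlap LD r-squared cutoff (strict).
#' @param alpha survival-scan significance level.
#' @param n_hidden_factors override for the 25%-of-n hidden factor count.
#' @param n_motif_loci motif loci simulated for the disruption stage.
#' @param seed master seed; stage streams derive from it.
#' @return validated `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(),
                            stages = c("simulate", "qc", "peaks", "annotate",
                              "map", "eqtl", "coloc", "mediate", "motif",
                              "gwas", "survival"),
                            cis_window = 1e6, fdr_threshold = 0.05,
                            min_samples = 2, min_spm = 5,
                            coloc_priors = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
                            prior_sd = 0.15, pp4_threshold = 0.8,
                            n_boot = 1000, ld_threshold = 0.5, alpha = 0.05,
                            n_hidden_factors = NULL, n_motif_loci = 40,
                            seed = 1L) {
  known <- c("simulate", "qc", "peaks", "annotate", "map", "eqtl", "coloc",
    "mediate", "motif", "gwas", "survival")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) abort("unknown stage(s): %s", paste(bad, collapse = ", "))
  structure(list(
    out_dir = out_dir, sim = sim, stages = stages, cis_window = cis_window,
    fdr_threshold = fdr_threshold, min_samples = min_samples,
    min_spm = min_spm, coloc_priors = coloc_priors, prior_sd = prior_sd,
    pp4_threshold = pp4_threshold, n_boot = n_boot,
    ld_threshold = ld_threshold, alpha = alpha,
    n_hidden_factors = n_hidden_factors, n_motif_loci = n_motif_loci,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Checks stage dependencies, sample-id intersections across the
#' simulated tables and chromosome-name consistency; issues are reported
#' rather than thrown.
#'
#' @param config a [pipeline_config()].
#' @param state optional in-progress pipeline state (internal).
#' @return data.frame(severity, message); zero rows = clean.
#' @export
validate_inputs <- function(config, state = NULL) {
  issues <- list()
  add <- function(sev, msg) issues[[length(issues) + 1]] <<- data.frame(
    severity = sev, message = msg, stringsAsFactors = FALSE)
  deps <- list(
    qc = "simulate", peaks = "simulate", annotate = "peaks",
    map = c("qc", "peaks"), eqtl = "qc", coloc = c("map", "eqtl"),
    mediate = "coloc", motif = "map", gwas = "map", survival = "map"
  )
  for (s in config$stages) {
    need <- deps[[s]]
    missing <- setdiff(need, config$stages)
    if (length(missing) > 0) {
      add("blocking", sprintf("stage '%s' requires stage(s): %s",
        s, paste(missing, collapse = ", ")))
    }
  }
  if (!is.null(state)) {
    if (!is.null(state$genotypes) && !is.null(state$survival)) {
      shared <- intersect(state$genotypes$samples, state$survival$donor)
      if (length(shared) == 0) {
        add("blocking", "no donors shared between genotypes and survival table")
      }
    }
    if (!is.null(state$genotypes) && !is.null(state$consensus)) {
      chr_g <- unique(state$genotypes$variants$chrom)
      chr_p <- unique(state$consensus$peaks$chrom)
      pref <- function(x) startsWith(x, "chr")
      if (length(chr_g) && length(chr_p) &&
          any(pref(chr_g)) != any(pref(chr_p))) {
        add("warning", "mixed chromosome naming ('chr1' vs '1'); normalize upstream")
      }
    }
  }
  if (length(issues) == 0) {
    return(data.frame(severity = character(0), message = character(0)))
  }
  do.call(rbind, issues)
}

## deterministic TSV writer
write_tsv_out <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the pipeline
#'
#' Executes the enabled stages in order on a synthetic cohort drawn from
#' `config$sim`, writing every stage's table and JSON summary under
#' `config$out_dir`. Re-running with an identical config reproduces
#' byte-identical TSVs.
#'
#' @param config a [pipeline_config()].
#' @param force run even when [validate_inputs()] reports blocking issues.
#' @return manifest data.frame (stage, artifact, path), invisibly the
#'   full state as attribute "state".
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  issues <- validate_inputs(config)
  if (any(issues$severity == "blocking") && !force) {
    abort("blocking validation issue: %s",
      issues$message[issues$severity == "blocking"][1])
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- new.env(parent = emptyenv())
  manifest <- list()
  emit <- function(stage, artifact, df, counts = list(), params = list()) {
    path <- file.path(config$out_dir, paste0(artifact, ".tsv"))
    write_tsv_out(df, path)
    write_stage_summary(file.path(config$out_dir, paste0(artifact, ".json")),
      stage, params, counts, seed = config$seed)
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, artifact = artifact, path = path,
      stringsAsFactors = FALSE)
  }
  need <- function(what, stage) {
    if (is.null(st[[what]])) {
      abort("stage '%s' requires missing upstream artifact '%s'", stage, what)
    }
    st[[what]]
  }
  run_stage <- list(
    simulate = function() {
      sim <- config$sim
      st$genotypes <- simulate_genotypes(sim)
      st$accessibility <- simulate_accessibility(st$genotypes, sim)
      st$expression <- simulate_expression(st$genotypes, st$accessibility, sim)
      st$survival <- simulate_survival(st$genotypes, sim)
      st$states <- simulate_state_track(sim)
      st$clinical <- with_seed(sim$seed + 5L, data.frame(
        donor = st$genotypes$samples,
        age = round(rnorm(sim$n_samples, 60, 10), 1),
        sex = sample(c(0L, 1L), sim$n_samples, replace = TRUE),
        stage = sample(1:3, sim$n_samples, replace = TRUE),
        stringsAsFactors = FALSE
      ))
      write_genotype_tsv(st$genotypes,
        file.path(config$out_dir, "genotypes.tsv"))
      write_peak_bed(st$accessibility$peaks,
        file.path(config$out_dir, "peaks_truth.bed"))
      if (nrow(st$expression$values) > 0) {
        write_matrix_tsv(st$expression$values,
          file.path(config$out_dir, "expression.tsv"), "gene")
      }
      write_survival_tsv(st$survival,
        file.path(config$out_dir, "survival_input.tsv"))
      emit("simulate", "clinical", st$clinical,
        counts = list(n_samples = sim$n_samples,
          n_variants = sim$n_variants, n_peaks = sim$n_peaks),
        params = list(seed = sim$seed))
    },
    qc = function() {
      geno <- need("genotypes", "qc")
      res <- filter_variants(geno)
      st$genotypes_qc <- res$genotypes
      st$pcs <- genotype_pca(res$genotypes,
        n_components = min(5, length(geno$samples) - 1))
      emit("qc", "qc_report", res$report,
        counts = as.list(attr(res$report, "counts")))
      emit("qc", "genotype_pcs",
        data.frame(donor = rownames(st$pcs), st$pcs, stringsAsFactors = FALSE),
        counts = list(n_components = ncol(st$pcs)))
    },
    peaks = function() {
      acc <- need("accessibility", "peaks")
      calls <- simulate_peak_calls(acc)
      calls <- lapply(calls, function(p) {
        p$score <- spm_normalize(p$score)
        p
      })
      cons <- build_consensus(calls)
      st$consensus <- filter_consensus(cons,
        min_samples = config$min_samples, min_spm = config$min_spm)
      df <- data.frame(st$consensus$peaks,
        n_samples_observed = st$consensus$n_samples_observed)
      emit("peaks", "consensus_peaks", df,
        counts = list(pooled = sum(vapply(calls, nrow, 0L)),
          consensus = nrow(cons$peaks), retained = nrow(st$consensus$peaks)),
        params = list(min_samples = config$min_samples,
          min_spm = config$min_spm))
      write_matrix_tsv(st$consensus$values,
        file.path(config$out_dir, "consensus_spm.tsv"), "peak")
    },
    annotate = function() {
      cons <- need("consensus", "annotate")
      track <- need("states", "annotate")
      labels <- assign_state(cons$peaks, track)
      sizes <- setNames(config$sim$chrom_length, config$sim$chrom)
      bg <- shuffle_background(cons$peaks[, c("chrom", "start", "end")],
        sizes, seed = config$seed + 10L)
      enr <- state_enrichment(cons$peaks, bg, track)
      st$peak_states <- data.frame(peak = cons$peaks$name, state = labels,
        stringsAsFactors = FALSE)
      emit("annotate", "peak_states", st$peak_states,
        counts = as.list(table(labels)))
      emit("annotate", "state_enrichment", enr,
        counts = list(n_background = nrow(bg)))
    },
    map = function() {
      geno <- need("genotypes_qc", "map")
      cons <- need("consensus", "map")
      clin <- need("clinical", "map")
      k <- config$n_hidden_factors %||%
        floor(0.25 * ncol(cons$values) + 0.5)
      k <- min(k, ncol(cons$values) - 2, nrow(cons$values) - 1)
      hf <- hidden_factors(cons, k = max(0, k))
      covs <- cbind(st$pcs,
        hf[match(rownames(st$pcs), rownames(hf)), , drop = FALSE],
        age = clin$age[match(rownames(st$pcs), clin$donor)],
        sex = clin$sex[match(rownames(st$pcs), clin$donor)],
        stage2 = as.integer(clin$stage[match(rownames(st$pcs), clin$donor)] == 2),
        stage3 = as.integer(clin$stage[match(rownames(st$pcs), clin$donor)] == 3))
      st$covariates <- covs
      st$caqtl <- map_caqtls(geno, cons, covs,
        window = config$cis_window, fdr_threshold = config$fdr_threshold)
      emit("map", "caqtl",
        cbind(st$caqtl, fdr_threshold = config$fdr_threshold),
        counts = list(tested = nrow(st$caqtl),
          significant = sum(st$caqtl$significant),
          peaks_with_caqtl = length(unique(
            st$caqtl$peak_id[st$caqtl$significant]))),
        params = list(cis_window = config$cis_window,
          n_hidden_factors = max(0, k)))
    },
    eqtl = function() {
      geno <- need("genotypes_qc", "eqtl")
      expr <- need("expression", "eqtl")
      if (nrow(expr$values) == 0) {
        st$eqtl <- st$caqtl[0, ]
        return(emit("eqtl", "eqtl", st$eqtl, counts = list(tested = 0)))
      }
      pseudo <- structure(list(
        peaks = data.frame(chrom = expr$tss$chrom,
          start = expr$tss$pos - 1L, end = expr$tss$pos,
          name = expr$tss$gene, stringsAsFactors = FALSE),
        values = expr$values
      ), class = "accessibility_matrix")
      st$eqtl <- map_caqtls(geno, pseudo, st$covariates,
        window = config$cis_window, fdr_threshold = config$fdr_threshold)
      names(st$eqtl)[names(st$eqtl) == "peak_id"] <- "gene_id"
      emit("eqtl", "eqtl", st$eqtl,
        counts = list(tested = nrow(st$eqtl),
          significant = sum(st$eqtl$significant)))
    },
    coloc = function() {
      ca <- need("caqtl", "coloc")
      eq <- need("eqtl", "coloc")
      st$coloc <- if (sum(ca$significant) == 0 || sum(eq$significant) == 0) {
        data.frame(peak_id = character(0), gene_id = character(0),
          lead_snp = character(0), n_snps = integer(0), pp0 = numeric(0),
          pp1 = numeric(0), pp2 = numeric(0), pp3 = numeric(0),
          pp4 = numeric(0), colocalized = logical(0))
      } else {
        pairs <- select_coloc_pairs(ca, eq, st$genotypes_qc)
        colocalize_pairs(pairs, ca, eq,
          p1 = config$coloc_priors$p1, p2 = config$coloc_priors$p2,
          p12 = config$coloc_priors$p12, prior_sd = config$prior_sd,
          pp4_threshold = config$pp4_threshold)
      }
      emit("coloc", "coloc", st$coloc,
        counts = list(pairs_tested = nrow(st$coloc),
          colocalized = sum(st$coloc$colocalized)),
        params = config$coloc_priors)
    },
    mediate = function() {
      cl <- need("coloc", "mediate")
      rows <- list()
      use <- cl[cl$colocalized, , drop = FALSE]
      for (r in seq_len(nrow(use))) {
        dos <- st$genotypes_qc$dosages[, use$lead_snp[r]]
        samples <- intersect(names(dos), colnames(st$consensus$values))
        med <- st$consensus$values[use$peak_id[r], samples]
        out <- st$expression$values[use$gene_id[r], samples]
        both <- mediate_both_directions(dos[samples], med, out,
          n_boot = config$n_boot, seed = config$seed + 20L + r)
        for (dir in c("forward", "reverse")) {
          m <- both[[dir]]
          rows[[length(rows) + 1]] <- data.frame(
            peak_id = use$peak_id[r], gene_id = use$gene_id[r],
            variant_id = use$lead_snp[r], direction = dir,
            acme = m$acme$estimate, acme_ci_low = m$acme$ci_low,
            acme_ci_high = m$acme$ci_high, acme_p = m$acme$p_value,
            ade = m$ade$estimate, ade_p = m$ade$p_value,
            te = m$te$estimate, te_ci_low = m$te$ci_low,
            te_ci_high = m$te$ci_high, te_p = m$te$p_value,
            prop_mediated = m$prop_mediated, n_boot = m$n_boot,
            stringsAsFactors = FALSE)
        }
      }
      st$mediation <- if (length(rows) > 0) do.call(rbind, rows) else
        data.frame(peak_id = character(0))
      emit("mediate", "mediation", st$mediation,
        counts = list(pairs = nrow(use)),
        params = list(n_boot = config$n_boot))
    },
    motif = function() {
      ca <- need("caqtl", "motif")
      n_loci <- config$n_motif_loci
      caqtl_snps <- unique(ca$variant_id[ca$significant])
      rows <- list()
      flags <- logical(n_loci)
      for (i in seq_len(n_loci)) {
        ## even loci carry a caQTL-linked disrupted motif, odd loci a
        ## variant outside any strong match
        is_caqtl <- i %% 2 == 0
        locus <- simulate_motif_locus(pwm_width = 8 + i %% 5,
          seed = config$seed * 1000L + i)
        ds <- disruption_score(locus$ref_sequence, locus$alt_sequence,
          locus$pwm, locus$variant_pos)
        disrupted <- !is.null(ds)
        flags[i] <- is_caqtl
        rows[[i]] <- data.frame(
          locus = i,
          variant_id = if (is_caqtl && length(caqtl_snps) > 0) {
            caqtl_snps[1 + (i %% length(caqtl_snps))]
          } else sprintf("locus_var_%03d", i),
          motif_id = locus$pwm$motif_id, is_caqtl = is_caqtl,
          disrupted = disrupted,
          log_ratio = if (disrupted) ds$log_ratio else NA_real_,
          direction = if (disrupted) ds$direction else NA_character_,
          stringsAsFactors = FALSE)
      }
      st$motif <- do.call(rbind, rows)
      emit("motif", "motif_disruption", st$motif,
        counts = list(loci = n_loci, disrupted = sum(st$motif$disrupted)))
    },
    gwas = function() {
      ca <- need("caqtl", "gwas")
      geno <- need("genotypes_qc", "gwas")
      sig <- unique(ca$variant_id[ca$significant])
      tags <- with_seed(config$seed + 30L, {
        pool <- geno$variants$id
        unique(c(head(sig, 3), sample(pool, min(10, length(pool)))))
      })
      gwas <- data.frame(
        variant_id = tags, trait = "synthetic_trait",
        chrom = geno$variants$chrom[match(tags, geno$variants$id)],
        pos = geno$variants$pos[match(tags, geno$variants$id)],
        stringsAsFactors = FALSE)
      st$gwas <- gwas_overlap(ca, gwas, geno,
        threshold = config$ld_threshold, window = config$cis_window)
      emit("gwas", "gwas_overlap", st$gwas,
        counts = list(gwas_tags = nrow(gwas), overlaps = nrow(st$gwas)),
        params = list(ld_threshold = config$ld_threshold))
    },
    survival = function() {
      ca <- need("caqtl", "survival")
      geno <- need("genotypes_qc", "survival")
      surv <- need("survival", "survival")
      vids <- unique(ca$variant_id[ca$significant])
      if (length(vids) == 0) vids <- head(geno$variants$id, 10)
      st$survival_scan <- suppressMessages(
        survival_scan(head(vids, 50), geno, surv, alpha = config$alpha))
      emit("survival", "survival_scan", st$survival_scan,
        counts = list(variants = length(unique(st$survival_scan$variant_id)),
          significant = sum(st$survival_scan$significant)),
        params = list(alpha = config$alpha))
    }
  )
  for (s in config$stages) {
    message("stage: ", s)
    run_stage[[s]]()
  }
  manifest <- do.call(rbind, manifest)
  write_tsv_out(manifest, file.path(config$out_dir, "manifest.tsv"))
  attr(manifest, "state") <- as.list(st)
  manifest
}
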