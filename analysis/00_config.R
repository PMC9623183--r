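# Shared settings for the analysis scripts: one synthetic tumor cohort
# with planted regulatory effects, analyzed end to end by the numbered
# drivers. Run the scripts in order from the repository root:
#
#   Rscript analysis/01_simulate_cohort.R
#   Rscript analysis/02_genotype_qc.R
#   ...
#
# Every script reads its inputs from results/ and writes its outputs
# there, so each stage can be rerun in isolation.

suppressMessages(library(caqtlkit))

RESULTS_DIR <- "results"
COHORT_SEED <- 42L

dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

cohort_config <- function() {
  # two caQTL peaks planted on the synthetic chromosome; one of them
  # drives a gene through accessibility (a = 3, b = 0.5, direct 0.5, so
  # the total genotype->expression effect is 2) and shortens survival
  # (hazard ratio 2 per minor allele)
  pe <- data.frame(variant_id = c("var_0010", "var_0050"),
    peak_id = c("peak_0005", "peak_0020"), beta = 3)
  ms <- data.frame(variant_id = "var_0010", peak_id = "peak_0005",
    gene_id = "gene_A", a = 3, b = 0.5, c_direct = 0.5)
  ss <- data.frame(variant_id = "var_0010", log_hazard = log(2))
  sim_config(n_samples = 80, n_variants = 120, n_peaks = 30,
    planted_effects = pe, mediation_specs = ms, survival_specs = ss,
    ld_rho = 0.6, noise_sd = 1, n_null_genes = 4, seed = COHORT_SEED)
}

res_path <- function(...) file.path(RESULTS_DIR, ...)
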