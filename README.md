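# caqtlkit

Chromatin accessibility QTL (caQTL) analysis for tumor cohorts, end to
end: from genotype and ATAC-seq peak quality control through cis-caQTL
mapping, caQTL–eQTL colocalization, causal mediation, transcription-factor
motif disruption, GWAS-locus overlap, and genotype-stratified survival.
The package is aimed at regulatory-genomics analysts who want each stage
of this pipeline as a tested, reusable R function, plus a synthetic-data
module that generates cohorts with planted effects so the whole chain can
be validated without any external data.

## The model in brief

For each variant *g* (dosage 0/1/2) and 501-bp consensus ATAC peak *y*
within 1 Mb, accessibility (score-per-million normalized) is modeled as

    y = μ + β·g + Cγ + ε

with covariates C (genotype PCs, hidden accessibility factors, age, sex,
stage). Significance is Benjamini–Hochberg FDR < 0.05 over all tested cis
pairs. Downstream:

* **Colocalization** — per-variant Wakefield approximate Bayes factors,
  log ABF = ½log(1−r) + z²r/2 with r = W/(V+W), summed over causal
  configurations to posteriors PP0..PP4; PP4 > 0.8 is a shared causal
  variant.
* **Mediation** — linear structural equations; ACME = a·b, ADE = c′,
  TE = a·b + c′, with a 1,000-resample nonparametric bootstrap, both
  causal directions reported.
* **Motif disruption** — exact PWM match p-values by dynamic programming;
  the allelic statistic is log10(p_weak) − log10(p_strong) with gain/loss
  calls, at variant ± 30 bp windows.
* **Survival** — log-rank scans under additive, dominant and recessive
  genotype codings, with O−E/V hazard ratios.

See `vignettes/caqtl-methods.Rmd` for assumptions, parameter defaults and
numerical choices.

## Worked example

The numbered scripts under `analysis/` run one synthetic cohort (80
donors, 120 variants, 30 peaks; two planted caQTLs, one mediated gene
with total effect 2, one survival variant with per-allele hazard ratio 2)
through every stage, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_genotype_qc.R
# ... through analysis/08_gwas_survival.R
```

Selected output (seed 42):

```
QC: 113/120 variants retained (removed: 7 MAF, 0 missing, 0 HWE, 0 INFO)
pooled 2400 per-sample calls -> 30 consensus peaks -> 30 after filters
caQTL: 3/620 pairs significant at FDR < 0.05 across 3 peaks
  variant_id      peak_id      beta            p          fdr distance_bp
1   var_0010  consensus_1 3012.1188 1.294918e-21 4.014245e-19           0
2   var_0050 consensus_11 2966.9786 8.925984e-23 5.534110e-20          -8
coloc: 1 candidate pair(s), 1 colocalized (PP4 > 0.8)
mediation (forward): ACME 0.953 (p = 0.014), ADE 0.708 (p = 0.0739), 57% mediated
40/40 planted loci called disrupted; all calls 'loss': TRUE
  variant_id    model group_sizes     chi2          p       hr
2   var_0010 dominant       31/49 4.468319 0.03452894 1.916062
```

Both planted caQTLs are recovered as lead associations (one at distance 0,
one 8 bp upstream of its peak); the mediated peak–gene pair colocalizes
with PP4 ≈ 1 and shows a significant forward ACME with ~57% of the total
effect mediated through accessibility; every planted motif locus is called
a "loss"; and the planted hazard variant is flagged by the dominant-model
log-rank scan with an estimated HR near 2. One additional caQTL pair at
FDR 0.037 is a false positive at this threshold — about what joint BH
control across 620 tests should deliver.

The same pipeline is available programmatically:

```r
library(caqtlkit)
cfg <- pipeline_config(out_dir = "results/run", sim = sim_config(seed = 1),
                       seed = 1)
manifest <- run_pipeline(cfg)
```

Re-running with an identical config reproduces byte-identical TSVs.

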