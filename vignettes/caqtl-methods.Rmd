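---
title: "Methods: caQTL mapping and downstream regulatory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: caQTL mapping and downstream regulatory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caqtlkit)
```

# Scope and model

A chromatin accessibility QTL (caQTL) is a genetic variant whose genotype
associates with the accessibility signal of an open-chromatin (ATAC-seq)
peak. `caqtlkit` implements the full desk-scale analysis around that idea:
genotype quality control, fixed-width peak construction and normalization,
chromatin-state annotation, cis-caQTL mapping, caQTL–eQTL colocalization,
causal mediation, allele-specific motif disruption, LD-based GWAS-locus
overlap, and genotype-stratified survival. A synthetic-data module generates
cohorts with planted effects so that every stage is testable without any
external download.

# Genotype quality control

Dosages are alt-allele counts in {0, 1, 2} with explicit missingness.
Variants are retained when

* imputation INFO ≥ 0.4 (skipped, with a notice, when no INFO is present),
* minor allele frequency ≥ 5% (inclusive),
* missing rate < 5% (strict), and
* exact Hardy–Weinberg p > 1e-6 (strict).

The HWE test is the exact conditional test: given the observed allele
counts, heterozygote configurations are enumerated and the p-value is the
total probability of configurations no more probable than the observed one.
A chi-square approximation would misbehave exactly where the filter
operates (p ≈ 1e-6), which is why the exact form is used. The mixed
strict/inclusive boundaries mirror the stated filter definitions and are
tested at the boundaries.

Population structure enters as the first five principal components of the
mean-imputed, centered dosage matrix. PCA uses no variance scaling
(1/sqrt(p(1-p)) weighting changes little at these scales and the simpler
convention is easier to reason about); signs follow the convention that the
largest-magnitude loading is positive, making results reproducible across
BLAS implementations.

# Peak processing

Peak summits are extended by 250 bp on each side, giving fixed 501-bp
intervals; peaks that would run past a chromosome end are dropped. All
coordinates are BED-style 0-based half-open.

Within and across samples, overlapping peaks are resolved by iterative
removal: keep the most significant peak, discard everything overlapping it
(≥ 1 bp), repeat. The implementation processes peaks in score order with an
interval-overlap index, which is provably equivalent to the literal loop;
the test suite checks equality against a brute-force O(n²) reference on
1,000 random instances. Score ties are broken by (chrom, start) so results
are deterministic.

Per-sample scores become score-per-million (SPM): score / total × 1e6,
making significance comparable across samples of different depth. The
consensus matrix pools all samples' SPM-scored peaks, reapplies iterative
removal, and quantifies each consensus peak per sample as the SPM of that
sample's best-overlapping own peak (largest overlap, ties to the higher
SPM), zero when absent. Consensus peaks are kept when observed in ≥ 2
samples, with maximum SPM ≥ 5, on autosomes, and off the blacklist. The
"over two samples" phrasing in the field's processing recipes is ambiguous
between ≥ 2 and > 2; the default is ≥ 2 with `min_samples` exposed so the
literal reading is selectable.

# Chromatin-state annotation

Raw 18-state segmentation labels merge to seven groups (promoter,
transcribed, enhancer, polycomb, ZNF/repeats, heterochromatin, quiescent).
A peak takes the state with the highest base-pair coverage — except
quiescent, which is assigned only at 100% coverage; when quiescent tops the
list but covers less than the whole peak, the runner-up wins. Coverage ties
break by a fixed priority (promoter > enhancer > transcribed > polycomb >
ZNF > heterochromatin) purely for determinism. Enrichment uses two-sided
Fisher tests with Woolf-logit 95% intervals (0.5 added to zero cells);
backgrounds come from width-preserving, same-chromosome uniform shuffles.

# cis-caQTL mapping

Hidden accessibility confounders are the top principal components of the
standardized peak × sample matrix — a deliberate surrogate for
variational factor models, keeping the stated count rule of one factor per
four samples (rounded half-up). At genome scale that rule is benign because
factors are few relative to features; in small synthetic cohorts with tens
of peaks it can absorb planted signal, so the bundled analyses fix the
count at 2 via `n_hidden_factors` and say so. Covariates further include
genotype PCs, age, sex, and dummy-coded tumor stage.

Candidate pairs are all variant–peak combinations on a chromosome within
1 Mb of the nearest peak edge (inclusive; distance 0 inside the peak). Each
pair is fit by OLS of phenotype on dosage + intercept + covariates, with
missing dosages dropped pairwise. When no dosage is missing the
implementation residualizes phenotypes and dosages on the covariates once
and reuses the pieces — algebraically identical to the per-pair fit and
checked against a normal-equations oracle at 1e-8. Benjamini–Hochberg FDR
is applied jointly over all tested pairs (the convention of the standard
matrix-QTL engines), and significance means FDR < 0.05, strict.

# Colocalization

Candidate peak–gene pairs follow a two-step rule: the lead caQTL per peak
(minimum p, ties by distance then id) selects genes whose significant eQTL
set contains that variant; among several genes, those whose own lead eQTL
maximizes r² with the lead caQTL are retained (exact ties kept, flagged).

Evidence sharing is assessed with per-variant approximate Bayes factors:
with V = se², z = β/se and r = W/(V+W), log ABF = ½log(1−r) + z²r/2, W
being the prior effect variance. Hypothesis sums over configurations (no
association; trait-1 only; trait-2 only; two distinct causal variants; one
shared causal variant) use priors p1 = p2 = 1e-4 and p12 = 1e-5 and are
evaluated in log space with log-sum-exp; posteriors PP0..PP4 are reported
and PP4 > 0.8 is called colocalized.

Because the prior SD (0.15) is defined on the standardized-effect scale,
summary statistics carrying a sample size are internally converted to
z/√n with standard error 1/√n. This makes the posteriors invariant to the
units of the phenotype (SPM values in the thousands would otherwise flatten
every ABF toward 1) and to joint rescaling of (β, se) — both properties are
under test.

# Mediation

Mediation uses linear structural equations without exposure–mediator
interaction: mediator ~ dosage (+ covariates) gives a; outcome ~ dosage +
mediator (+ covariates) gives c′ and b. ACME = a·b, ADE = c′, TE = a·b + c′
exactly — an identity asserted to 1e-8 on every fit. Uncertainty comes from
a nonparametric case-resampling bootstrap (default 1,000 resamples):
percentile 95% intervals and two-sided sign-based p-values with a +1
continuity correction, floored at 2/(B+1). Resamples with constant dosage
are redrawn and counted. With no covariates the bootstrap uses closed-form
centered-moment algebra vectorized across resamples; the tests replay the
same resample indices through `lm()` to confirm exact agreement. Both
causal directions (accessibility→expression and the reverse) are always
computed and reported, since the data alone cannot pick the direction.

A note on calibration: when both a = 0 and b = 0, the bootstrap test of the
product a·b is intentionally conservative (the product's distribution
degenerates); the ~5% type-I behavior is tested under the singly-null
regime (a = 0, b ≠ 0), which is the case of scientific interest.

# Motif disruption

For each variant, the reference and alternative alleles are embedded in
61-mers (variant ± 30 bp). PWMs are pseudocount-smoothed (0.01) log2
likelihood ratios against a uniform background — uniform, rather than
sequence-derived, because 61-mers are too short to estimate a background
well; the background is configurable. Match p-values are exact tail
probabilities of the background score distribution computed by dynamic
programming over a finely discretized score lattice (1/20,000 of the mean
per-column score range, with a half-lattice slack so threshold ties count
as matches); exhaustive 4^w enumeration confirms agreement within 1e-3 for
widths ≤ 8.

Per allele, all windows on both strands covering the variant position are
scanned and the most significant hit kept; a locus is reported only when
some allele matches below p < 1e-4. The disruption statistic is
log10(p_weak) − log10(p_strong) ≥ 0, with direction "loss" when the
reference allele matches better and "gain" otherwise. Association of
disruption with caQTL status is per-motif Fisher; concordance asks whether
the stronger-match allele is the more accessible allele (from the caQTL β
sign under alt-dosage coding).

# LD and GWAS overlap

LD is the squared Pearson correlation of dosage vectors over jointly
non-missing samples — the composite convention, which tracks haplotype r²
closely at HWE; this replaces external LD services so the analysis is
self-contained, and the divergence is documented rather than hidden. A
GWAS tag's LD region is every variant within 1 Mb with r² strictly above
0.5; caQTL SNPs inside a region are reported with the tag, trait, r², and
a direct-overlap flag.

# Survival

Dosages are recoded to minor-allele counts within the analyzed cohort
(recoding logged). The additive model keeps three genotype groups; dominant
merges heterozygotes with minor-allele homozygotes; recessive merges them
with major-allele homozygotes — partitions that must sum to the cohort, an
invariant under test. The k-sample log-rank test (hypergeometric
expectations, standard tie correction) is delegated to the survival
package; the two-group hazard ratio is exp((O₂−E₂)/V) with 95% CI
exp(±1.96/√V) from the same quantities — an approximation to the partial-
likelihood estimate, chosen because it derives from exactly the statistic
the scan already computes. Monomorphic variants and event-free strata are
flagged untestable rather than erroring.

# The synthetic cohort

The generator is first-class, tested code; its defaults define the study
conditions:

* Genotypes: per-variant MAF uniform in the configured range, marginals
  exactly HWE via a Gaussian-copula construction; within LD blocks a
  latent AR(1) with parameter `ld_rho` induces dosage correlation. This
  reproduces pairwise r² targets approximately, which is all the
  downstream analyses consume.
* Accessibility: log-normal positive baselines (SPM-like scale), additive
  planted β per alt allele, Gaussian noise; peaks occupy non-overlapping
  501-bp slots on a 1-kb grid of a single synthetic chromosome (default
  10 Mb), with planted peaks pinned near their causal variants so pairs
  sit inside the cis window.
* Expression: gene = c′·dosage + b·peak + noise, so TE = a·b + c′ by
  construction.
* Survival: exponential event times with hazard h₀·exp(Σ log-HR·dosage),
  h₀ = 1/1000 per day; censoring marks each donor independently with the
  configured probability at a uniform fraction of the event time.
* Motif loci: an informative PWM (88% consensus base per column), its
  consensus embedded across the central variant of a random 61-mer, and an
  alternative allele substituting the least-preferred base — a guaranteed
  "loss" locus.

What the generator does not emulate: read-level counts and their
overdispersion, peak-width variation, population stratification,
linkage beyond block-local AR(1), genotype uncertainty from imputation,
and informative censoring. Passing tests therefore demonstrate
correctness of the statistical machinery under its stated assumptions,
not robustness to every failure mode of real tumor data.

# Problem sizes and numerical choices

The bundled analyses and the acceptance script use desk-scale cohorts
(about 80–400 donors, 100–120 variants, 20–30 peaks, bootstrap 200–1,000,
50–300 replicates per calibration claim); these sizes were chosen so the
whole suite exercises every stage in minutes while keeping each claim's
Monte-Carlo error well inside its asserted band. Degenerate inputs are
first-class: all-missing dosage vectors, zero-score SPM inputs,
monomorphic variants in LD, rank-deficient designs, event-free survival
strata and zero-margin 2×2 tables all return flagged results or named
errors, and are tested.

Known limitations: the PEER surrogate is PCA (deliberate); the hazard
ratio is the O−E/V approximation, not a Cox fit; colocalization assumes a
single causal variant per trait per region; mediation assumes sequential
ignorability and linearity, and no sensitivity analysis is provided.
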