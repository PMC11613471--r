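---
title: "Models and methods behind stimqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stimqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stimqtl)
```

`stimqtl` analyses paired stimulation designs: the same donors' cells are
profiled untreated (control) and under one or more genotoxic stimuli, with
genome-wide genotypes from the untreated cells. The scientific object of
interest is the *response eQTL* (e²QTL): a cis-regulatory variant whose
effect on a gene's expression changes when the cell is stimulated. This
vignette describes each model in the chain, the tunable parameters that
matter, the numerical choices, and what the synthetic benchmark does and
does not demonstrate.

## Variant and sample quality control

Variant filters mirror standard array QC: minor allele frequency > 5%, call
rate > 97%, and Hardy–Weinberg equilibrium. HWE is tested with the exact
conditional (Levene–Haldane) test: given the allele counts, the heterozygote
count has a known discrete distribution, and the two-sided p-value sums the
probabilities of all configurations no more probable than the observed one.
We chose the exact test over the chi-square approximation because it is
well-defined at any sample size and is directly checkable against a
full-enumeration oracle; probabilities are accumulated in log space with a
`(1 + 1e-12)` slack on the probability comparison to make ties robust to
rounding. The package applies the filters with strict inequalities and
attributes each removal to the first failing filter in the order call rate,
MAF, HWE. At the eQTL stage the filter is re-applied per analysis dataset
with the looser HWE threshold of 1e-6 and no call-rate requirement.

Population stratification is captured by PCA of the mean-imputed,
column-standardized dosage matrix (top 3 PCs by default); each component's
sign is fixed so its largest-magnitude loading is positive, making scores
reproducible across runs. Sample-level array QC (sex checks, kinship,
heterozygosity) is out of scope; the genotype PCs are the stratification
covariates.

Expression outliers are detected per control/stimulus pair: top two PCs of
the pooled log-CPM matrix, then a two-component full-covariance Gaussian
mixture fitted by EM. Initialization is a deterministic, order-invariant
k-means seeded at the samples nearest the 10th and 90th percentile of PC1,
so flags do not depend on sample order. Because no published rule defines
"outlier" here, two configurable criteria are used: (i) mixture density
below the 0.1% quantile of the fitted mixture's own density distribution
(Monte-Carlo estimate, fixed seed), and (ii) assignment to a cluster other
than the one dominating the sample's condition. Criterion (ii) is disabled
when more than 20% of samples mismatch, which indicates the clustering does
not track condition at all, and both criteria are skipped when the PC scores
are degenerate (e.g. duplicated samples).

## Differential expression

Counts are normalized with trimmed-mean-of-M-values (TMM) factors: the
reference sample is the one whose 75th count-fraction percentile is closest
to the sample mean; gene-wise log ratios are double-trimmed (30% on M, 5% on
A) and averaged with inverse asymptotic-variance weights. log₂-CPM uses a
0.5 prior count scaled by library size, so exactly proportional samples map
to identical columns. Genes below 1 CPM in more than 80% of samples are
filtered by default.

Per-gene linear models of log-CPM on the condition indicator (plus
covariates) are moderated by empirical-Bayes shrinkage: the residual
variances are assumed to follow a scaled inverse-chi-square prior whose
degrees of freedom d₀ and scale s₀² are estimated by matching the first two
moments of the log residual variances (with a Newton inverse-trigamma
solver), and the moderated t statistic uses the shrunken variance on
d + d₀ degrees of freedom. This reimplements the standard limma-style
moderation on log-CPM directly; the mean–variance precision weighting of
voom is deliberately not applied, a documented divergence that matters
little at the read depths the generator emulates. Forcing `prior_df = Inf`
recovers the pooled common-variance t-test exactly, which the tests use as a
closed-form limit check, and the estimates are cross-checked against limma
itself.

A gene is a DEG in a stimulus when adjusted p < 0.05 *and* |log₂FC| > 1.5,
both strict, with BH adjustment across genes. DEGs significant in exactly
one stimulus are "specific"; the default "common" rule is significance in
two or more stimuli, with an alternative all-stimuli rule behind
`common_rule = "all"` because the two definitions circulate in the
literature describing such designs. Fold changes are base-2 throughout.

Enrichment is generic over user-supplied gene sets: over-representation uses
the hypergeometric upper tail P(X ≥ overlap) with the post-filter gene
universe as the default background (standard practice; the universe is
configurable). GSEA uses the weighted Kolmogorov–Smirnov running sum
(hits weighted by |score|^w, w = 1 by default; misses by 1/(N−N_h)) with a
gene-label permutation null, sign-stratified normalization (NES) and BH
correction across sets. When a set covers the entire ranking the miss
increment is taken as i/N, the natural uniform limit, so the running sum
still ends at zero.

## cis-eQTL mapping

Expression preparation follows the GTEx recipe: expression filtering, TMM
log-CPM, a per-gene rank-based inverse-normal transform
Φ⁻¹((r − 0.5)/n) (average ranks for ties), then residualization on
covariates. Hidden confounders are captured by the top PCs of the
transformed matrix rather than PEER factors: the role is identical and the
count is a configuration knob (`n_expr_factors`, default 15 for
synthetic-scale data; the pipeline runs in this package use 3–5 because the
simulated studies have hundreds, not tens of thousands, of genes). The
benchmark below shows one caveat of any hidden-factor correction: if a large
fraction of genes carry strong planted genetic effects through a handful of
LD blocks, the factors absorb genetic signal; at realistic eGene sparsity
(~10% of genes) this does not occur.

Candidate pairs are all variants within ±1 Mb of a gene's TSS, boundary
inclusive, with signed distance `pos − tss` regardless of strand. The
nominal scan is a per-variant simple regression of the residualized
expression on dosage (covariates are projected out once, not refitted per
variant — the same two-stage strategy as FastQTL-class tools). The t-test
uses n − 2 degrees of freedom by default with a configurable adjustment for
the projected covariate count. Missing dosages are mean-imputed;
zero-variance variants are skipped.

Gene-level calibration follows the permutation/beta scheme: the expression
vector is permuted, the minimum nominal p across the gene's cis variants
recorded per permutation, and a Beta(a, b) distribution fitted to the
permuted minima by maximum likelihood (Nelder–Mead on log-shape parameters,
method-of-moments initialization and fallback). The adjusted p-value is the
fitted Beta CDF at the observed minimum. Permutations are adaptive: 1,000
are run first, extended to 10,000 when fewer than 10 permuted minima reach
the observed minimum. The direct permutation p-value `(1 + hits)/(1 + B)` is
reported alongside. One numerical subtlety: the observed minimum is computed
through the identical max-|r| transform used for the permuted minima, so the
two are comparable to the last ulp (the slope/se path can differ by one
rounding step at p ≈ 1). Permuted minima are clamped to
[1e-12, 1 − 1e-12] before the Beta likelihood.

Gene-level q-values default to BH across genes; the Storey variant
(π₀ estimated at λ = 0.5) is available behind a flag but BH is the default
because the synthetic studies test tens to hundreds of genes, where π₀
estimation is unstable. eGenes are genes with qval < 0.05.

## Response eQTL

For each gene the top variant is, by default, the one with the smallest
nominal p across the two conditions' gene-level top records, with exact ties
broken by smaller |TSS distance| and then lexicographic variant id; control-
or stimulus-anchored selection is available because the defining condition
is a genuine design choice. Slopes and standard errors for the selected
variant are refitted in both conditions and compared with
z = (β_stim − β_ctrl)/√(se²_stim + se²_ctrl), two-sided normal p, Bonferroni
over the genes tested in that condition pair (per-condition correction
matches per-stimulus reporting). The test treats the two estimates as
independent although the donors are paired; the shared-donor correlation is
inherited from the method this follows and is not corrected — at the
simulated noise levels it leaves the type-I error within [0.04, 0.06] (the
acceptance suite verifies this), but it is a known caveat.

## LD and colocalization

LD is the squared Pearson correlation of dosages (composite LD) computed
from the local genotype matrix — phase-free, allele-flip invariant, and
hermetic (no remote reference service); it can differ from haplotype-based
reference-panel r². Colocalization assumes a single causal variant per
trait per locus: per-variant Wakefield log approximate Bayes factors
(prior effect SD 0.15 for quantitative traits, 0.2 for log odds ratios;
SE-based variance only — MAF-based reconstruction is not implemented, an SE
column is required) are combined into the five hypothesis weights
1, p₁S₁, p₂S₂, p₁p₂(S₁S₂ − S₁₂), p₁₂S₁₂ with default priors
p₁ = p₂ = 1e-4, p₁₂ = 1e-5. All sums are in log space; the H3 pair sum over
distinct variants is evaluated with exact leave-one-out log-sums for loci up
to 512 variants (and a scaled subtraction beyond), which keeps it
non-negative and accurate even when one variant dominates both traits — a
plain S₁S₂ − S₁₂ subtraction loses several digits exactly in the
near-colocalized regime one cares about. Effect alleles are harmonized on
the shared variants before combination. The default locus is the gene's cis
window.

The trait-association table emits, per (gene, trait, condition): e²QTL-class
records for Bonferroni-significant e²QTL that are significant eQTL
(qval < 0.05) with r² > 0.7 between the GWAS variant and the top variant;
and eQTL-class records that additionally require strong differential
expression (adj. p < 0.05, |log₂FC| > 2) — the DE requirement applies to the
eQTL class only, by design. GWAS hits are filtered to genome-wide
significance (p < 5e-8) on read. A GWAS hit may tag several genes; no
best-gene pruning is applied.

## The synthetic generator

The generator's defaults emulate the paired six-condition CD8⁺ T-cell
design: 461 donors, conditions CTRL, BPDE, HC, MMS, TBOOH, UVC, ~10M reads
per sample. Genotypes use haplotype copying: within an LD block each
haplotype's latent uniform is copied from the previous variant with
probability `ld_decay` (default 0.9) and redrawn otherwise, giving
geometrically decaying r² with exact per-variant allele frequencies drawn
from `maf_range`. This is deliberately not a coalescent — it provides
tunable, desk-scale LD sufficient for the LD/colocalization analyses, not
population-genetic realism (no recombination hotspots, no allele-frequency/
LD coupling, one chromosome, no sex chromosomes).

Expression is negative-binomial: gene baselines from a heavy-tailed Dirichlet
weight vector, log-normal library sizes, dispersion 0.1 by default (a free
parameter — the emulated study reports no per-gene dispersions — in the
range typical of bulk RNA-seq), condition log₂ fold changes for a
configurable DEG fraction whose sign is negative with per-stimulus
probability spanning the 85–99% repression range observed across stimuli
(HC lowest at 0.85, UVC highest at 0.99, the unreported stimuli interpolated
at 0.90–0.95), and planted cis-eQTL acting multiplicatively on the mean,
`exp(slope · dosage)`, with condition-specific slopes (stimulus slopes
default to 0.4× control, modelling the observed attenuation). Genotype
effects act on the log mean because downstream mapping is rank-based and
scale-free. Same donors appear in every condition (paired design);
missingness defaults to 0 and is configurable to exercise the call-rate
filter. The generator does not emulate: GC/length biases, isoform structure,
batch-confounded designs, RNA degradation, or trans effects.

GWAS cohorts re-use the stored LD recipe (frequencies, blocks, copy
probability) at any cohort size, with marginal per-variant regressions on a
phenotype driven by one causal variant (linear for quantitative traits,
logistic for case-control).

## Benchmark sizes and what they show

The test-suite and acceptance-script studies are scaled to run on one CPU in
a few minutes, sizes chosen as the smallest at which the checked property is
statistically clean: null calibration of the permutation pass uses 500 genes
× 200 donors × 30 cis variants; beta-approximation fidelity 50 genes at
10,000 permutations; e²QTL type-I error 2,000 genes; e²QTL power 50
replicates at the strongest observed attenuation (|Δβ| = 0.7, MAF 0.3,
n = 400, unit noise); colocalization discrimination 50 replicates each of
shared and distinct causal variants (eQTL n = 400, GWAS n = 10,000,
within-block r² ≈ 0.95); repression emulation 2,000 genes with 500 true
DEGs; attenuation recovery 300 genes with 30 planted eQTL (~10% eGene
density). Passing these shows the inference chain is calibrated and powered
under the generator's assumptions; it does not certify performance on real
data with unmodelled structure (batch effects, cell-type composition,
reference-panel LD mismatch).

## Known limitations

- Single-causal-variant colocalization; no multi-signal or conditional
  analysis, no fine-mapping.
- The e²QTL z-test ignores the shared-donor covariance between conditions.
- Expression-factor correction can absorb genetic signal when eGene density
  is extreme; the factor count is a knob, not an estimate.
- Composite dosage r² is not reference-panel haplotype r².
- Trans-eQTL, interaction terms inside the scan, and read-level simulation
  are out of scope.
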