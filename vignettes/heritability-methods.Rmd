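---
title: "Estimating SNP and twin heritability with heritkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating SNP and twin heritability with heritkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heritkit)
```

## The model

heritkit estimates how much phenotypic variance is captured by common SNPs.
The engine is the GRM mixed linear model: for a phenotype vector $y$ with
fixed effects $X\beta$,

$$ V = \mathrm{Var}(y) = \sum_c G_c\,\sigma^2_c + I\,\sigma^2_e, $$

where each $G_c$ is a genetic relationship matrix built from a set of SNPs
(one genome-wide set, or one set per annotation category) and $I$ is the
identity, i.e. independent residuals. SNP heritability is the variance
proportion $h^2_c = \sigma^2_c / (\sum_c \sigma^2_c + \sigma^2_e)$ — a lower
bound on narrow-sense heritability because only genotyped/imputed common
variants enter $G$.

The GRM uses standardized dosages with in-sample allele frequencies $p_i$:
off-diagonals average $(x_{ij} - 2p_i)(x_{ik} - 2p_i)/(2p_i(1-p_i))$ over
SNPs non-missing in both subjects; the diagonal defaults to the
inbreeding-adjusted form used by the GRM-binary ecosystem
(`compute_grm(..., diagonal = "simple")` gives the squared-standardized
alternative; the two agree in expectation under Hardy–Weinberg but differ
subject by subject). Because frequencies are estimated in-sample, unrelated
off-diagonals centre slightly below zero (about $-1/(n-1)$); at cohort sizes
this is negligible, but it matters when interpreting planted-relatedness
values in very small test cohorts.

Variance components are estimated by restricted maximum likelihood. The
criterion is the full log-likelihood of an orthonormal error-contrast basis,

$$ \ell(\sigma^2) = -\tfrac12\left[\log|V| + \log|X^\top V^{-1}X|
   - \log|X^\top X| + y^\top P y + (n-p)\log 2\pi\right], $$

with $P = V^{-1} - V^{-1}X(X^\top V^{-1}X)^{-1}X^\top V^{-1}$. Keeping all
constants makes the value exactly equal to the multivariate-normal density of
the contrasts, so independent evaluations can be compared to machine
precision rather than "up to a constant".

`reml_fit()` runs average-information (AI) REML with two EM-REML warm-up
iterations, step-halving when a proposed update is infeasible or decreases
the likelihood, and nonnegativity enforced by flooring; a component that
repeatedly presses against zero is fixed there and the rest refitted.
Standard errors come from the inverse AI matrix at the optimum, and variance
proportions get delta-method standard errors. Convergence is declared when
the log-likelihood moves by less than `tol` (default 1e-8).

### A numerical choice: the spectral path

With a single GRM, $V$ is diagonal in the GRM eigenbasis, so every AI-REML
quantity is computable in $O(np^2)$ per iteration after one
eigendecomposition. `reml_fit()` uses this path automatically for
one-component models and dense linear algebra otherwise; both paths are
tested to agree on the likelihood, gradients and AI matrix. This is what
makes replicate-heavy validation (twenty 2000-subject fits in a test run)
practical.

### Testing a component

Dropping a variance component pins it to the boundary of its parameter
space, so the likelihood-ratio statistic is compared to the 50:50 mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ rather than a plain $\chi^2_1$
(`lrt(..., mixture = FALSE)` gives the plain version; dropping several
components falls back to a conservative $\chi^2_q$ with a warning). Under
the mixture, a statistic of 2.706 corresponds to p = 0.05, and 7.10 to
p ≈ 0.004 — the Bonferroni level for a 12-phenotype atlas. `estimate_h2()`
wires the pieces together: per-category GRMs, the top GRM eigenvectors
appended to the covariates as ancestry controls (10 by default), full and
reduced fits, and a per-component LRT.

Covariates can enter either as fixed effects inside the REML fit (the
default in `estimate_h2()`) or by residualizing phenotypes beforehand with
`residualize()`; both pathways are supported because regional-imaging
pipelines traditionally pre-adjust, while mixed-model practice keeps
covariates in the model.

## Annotation partitioning

`annotate_genic()` labels a SNP genic when its position falls inside a gene
span extended by 20 kb on each side — a definition under which genic and
intergenic genome coverage are roughly equal. BED input is 0-based
half-open; everything internal is 1-based closed, with the conversion
centralized at the reader.

Conservation scores are smoothed by linkage disequilibrium before
partitioning, so that a tagging SNP inherits the annotation of the variants
it tags. `ld_weight_scores()` uses the self-inclusive r²-weighted average

$$ \tilde s_i = \frac{\sum_j r^2_{ij}\, s_j}{\sum_j r^2_{ij}}, $$

summing over scored SNPs within the LD window (1 Mb by default, r² with
unit diagonal). The normalization is a deliberate design choice: the raw
matrix–vector product (`normalize = FALSE`) changes the scale of the scores,
while the weighted average is a convex combination — it preserves the score
range and maps a constant track to itself, which makes downstream median
splits comparable to splits of the raw scores. SNPs with no score and no
scored LD partner get a missing weighted score and are dropped, mirroring
how unscored genome positions are discarded in practice. `median_split()`
then thresholds at the median (ties go low), giving low/high categories of
near-equal size, and `build_partition()` turns category labels into disjoint
SNP sets for per-category GRMs.

## The twin arm

`fit_ace()` implements the classical twin decomposition by direct maximum
likelihood on the 2×2 covariance structures — MZ pairs share all of the
additive genetic variance A and the common environment C, DZ pairs half of
A and all of C — rather than through a path-model engine; the estimand is
identical and the closed-form sufficient statistics make the likelihood
cheap and verifiable. Optimization is BFGS on log-variances with
moment-based starting values (Falconer estimates from the observed
intraclass correlations, clipped away from the boundary); the AE, CE and E
submodels are fitted for likelihood-ratio comparison. `twin_correlations()`
reports double-entry (pair-symmetrized) intraclass correlations, and
`falconer()` gives the moment decomposition
$a^2 = 2(r_{MZ} - r_{DZ})$, $c^2 = 2r_{DZ} - r_{MZ}$, $e^2 = 1 - r_{MZ}$,
untruncated.

## What the synthetic cohorts emulate

All validation runs on generated data with known truth, because the kind of
cohort this analysis targets (thousands of genotyped subjects with imaging
phenotypes) cannot ship with a package.

* **Genotypes** (`simulate_genotypes()`): two haplotypes per subject;
  within an LD block alleles follow a stationary first-order copy chain
  whose lag-1 correlation is `ld_rho` exactly; blocks are independent.
  When `ld_rho > 0` the SNPs of a block share one allele frequency drawn
  uniformly from `maf_range` — with mismatched frequencies the target
  correlation is mathematically unattainable, so per-SNP draws are reserved
  for `ld_rho = 0`. Positions are 1-based at fixed 1 kb spacing on one
  synthetic chromosome: interval logic stays testable without real maps.
* **Annotation** (`simulate_annotation()`): non-overlapping genes placed one
  per equal-width slot with uniform jitter, sized so the *flanked* genic
  span covers `frac_genic` of the region (targeting the raw span instead
  would inflate the genic SNP fraction well past the requested coverage
  once the ±20 kb flanks are applied); Beta-distributed conservation scores
  with block-level spatial autocorrelation and an elevated mean inside gene
  bodies; a configurable fraction of SNPs is left unscored.
* **Phenotypes** (`simulate_phenotype()`): standardized-genotype effects
  drawn per category with variance $h^2_c/m_c$, a nonlinear age trend, sex
  and cohort effects, and Gaussian noise of variance $1 - h^2_{total}$. By
  default the realized genetic values are rescaled so the realized
  heritability equals the target *exactly* (per-category shares first, then
  one joint rescale that preserves their ratios) — this makes
  parameter-recovery checks sharp; `rescale_exact = FALSE` reverts to
  random realized heritability around the target.
* **Relatedness** (`plant_relatedness()`): pair member two is re-drawn to
  share one haplotype in a fraction `2k` of blocks (sampled consistently
  from member one's genotype), giving an expected GRM entry of `k`.
* **Twins** (`simulate_twins()`): bivariate normal pairs at the ACE-implied
  correlations, defaulting to 134 MZ and 99 DZ pairs with
  $(a^2, c^2, e^2) = (0.60, 0.02, 0.38)$, i.e. population correlations
  0.62 and 0.32.

What the generator does *not* model: coalescent or demographic structure,
imputation-dosage uncertainty, the X chromosome, genotyping batch effects,
or real gene geometry. Passing tests therefore demonstrate that the
estimators recover the parameters of this generating process at realistic
sizes — they do not certify behaviour under ancestry admixture or
assay artefacts beyond what the planted-structure PCA checks cover.

## Quality control and pruning

`qc_filter()` applies, in a fixed documented order: sample missingness
(> 5%), minor allele frequency (< 1%, computed as mean dosage / 2 so
fractional imputed dosages contribute), a deterministic 1-df chi-square
Hardy–Weinberg test (p < 1e-6; an exact test could be swapped in, but the
chi-square matches classical toolchain behaviour at common MAF), and
sample heterozygosity outliers (> 5 s.d., hard calls only). Because the
heterozygosity pass depends on the retained set, `qc_fixpoint()` iterates
to a fixpoint (reached within a handful of passes on well-behaved data).

`prune_related()` removes cryptic relatedness greedily: while any GRM entry
exceeds the threshold, drop the subject in the most offending pairs, ties
broken by input order (deterministic, and within one subject of the
exhaustive optimum on all small instances tested). The conventional
thresholds 0.025 and 0.1 are both supported and the pipeline can report
them side by side as a robustness check. A caveat that matters at package
scale: with $M$ effective markers the GRM off-diagonal noise is
$O(1/\sqrt M)$, so a 0.025 threshold is only meaningful when
$1/\sqrt{M_{\mathrm{eff}}} \ll 0.025$; demonstrations use dense independent
markers for exactly this reason.

## Problem sizes used in validation

The test suite fits twenty replicates at n = 2000 subjects × 8000 SNPs for
genome-wide recovery (truth 0.45), twenty at n = 1200 × 4000 for the
two-category partition (truth 0.30/0.10), two hundred null replicates at
n = 500 × 1000 for LRT calibration, and fifty twin replicates at the
134 MZ / 99 DZ design size. These sizes were chosen so that sampling noise
is small relative to the recovery bands being asserted while a full
validation run stays comfortably interactive on one workstation core.

## Known limitations

* Single-phenotype univariate REML only: no bivariate/genetic-correlation
  models, and no single-SNP association testing.
* The LD weighting scheme is the package's own normalization of "apply the
  LD matrix to the score vector"; alternatives (raw product, signed r)
  exist and the raw product is available behind a flag.
* The six-way genic sub-annotation (exon/intron/UTRs/flanks) is supported
  structurally as any ≥ 2-category partition, but only genic/intergenic and
  conservation low/high are first-class, tested modes.
* ACE only for twins (no ADE, sex-limitation or covariate moderation);
  twin phenotypes are assumed pre-adjusted.
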