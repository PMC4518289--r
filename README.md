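# heritkit

Tools for asking how much of a quantitative trait's variation is captured by
common genetic variants — and where in the genome that signal lives.

The package is aimed at statistical geneticists and imaging-genetics groups
who work with cohorts of genotyped subjects (PLINK filesets, GCTA GRM
binaries) and regional phenotypes such as cortical surface area. It
implements, end to end:

* **SNP heritability** via the GRM mixed linear model
  `V = Σ_c G_c σ²_c + I σ²_e`, fitted by average-information REML with
  EM warm-up, nonnegativity constraints and inverse-AI standard errors.
  `h²_c = σ²_c / (Σ σ²_c + σ²_e)` is the proportion of phenotypic variance
  captured by the SNPs behind component `c`, and each component is tested
  against zero with a boundary-mixture (`½χ²₀ + ½χ²₁`) likelihood-ratio
  test.
* **Annotation partitioning**: genic/intergenic labelling (gene spans
  ±20 kb), windowed pairwise LD (r²) matrices, LD-weighted smoothing of
  per-SNP conservation scores (`s̃_i = Σ_j r²_ij s_j / Σ_j r²_ij`), median
  splits into low/high-conservation SNP sets, and joint multi-GRM fits of
  the resulting partitions.
* **Classical twin analysis**: double-entry intraclass correlations, direct
  maximum-likelihood ACE fits on MZ/DZ pair covariance structures
  (`cov_MZ = a² + c²`, `cov_DZ = a²/2 + c²`), nested AE/CE/E comparisons,
  and the Falconer moment decomposition `a² = 2(r_MZ − r_DZ)`.
* **The plumbing around the models**: PLINK .bed/.bim/.fam and GCTA
  .grm.bin/.grm.N.bin/.grm.id I/O, genotype QC (missingness, MAF,
  Hardy–Weinberg, heterozygosity), greedy cryptic-relatedness pruning at
  0.025/0.1, GRM principal components as ancestry covariates, and
  parcel-to-phenotype preparation (membership-weighted regional areas,
  global normalization, spline-based covariate adjustment).
* **A synthetic-data generator** (`sim_config()`, `simulate_*()`) producing
  LD-blocked genotypes, structured annotations, polygenic phenotypes with
  per-category enrichment, planted cryptic relatedness and ACE twin pairs —
  with known ground truth, so every stage is testable without any download.

Results come back as tibbles; fitted objects support `tidy()`, `glance()`
and `autoplot()`. See `vignette("heritability-methods")` for the models,
assumptions and design choices.

## Worked example

Simulate a cohort whose trait draws 30% of its variance from genic SNPs and
10% from intergenic SNPs, then recover that partition jointly:

```r
library(heritkit)

cfg <- sim_config(n_subjects = 800, n_snps = 4000,
                  h2_by_category = c(genic = 0.30, intergenic = 0.10),
                  h2_total = 0.40, seed = 42)
geno  <- simulate_genotypes(cfg)
genes <- simulate_annotation(geno$snp_map, cfg)$genes
track <- annotate_genic(geno$snp_map, genes, flank_bp = 20000)
sim   <- simulate_phenotype(geno, track[, c("snp_id", "category")], cfg)

fit <- estimate_h2(
  geno, sim$phenotypes[, c("fid", "iid", "y")],
  covariates = sim$phenotypes[, c("fid", "iid", "age", "sex", "cohort")],
  partition  = build_partition(track),
  n_pcs = 10)
fit
#> # A tibble: 3 × 10
#>   phenotype component  sigma2     se  prop prop_se loglik lrt_stat    p_value
#> 1 y         genic       0.258 0.0744 0.255  0.0695 -1104.    14.8   0.0000600
#> 2 y         intergenic  0.119 0.0715 0.117  0.0697 -1104.     2.94  0.0432
#> 3 y         residual    0.635 0.0958 0.627  0.0968 -1104.    NA    NA
```

The `prop` column is the estimated variance share per component — here the
genic share is 0.26 (truth 0.30) and the intergenic share 0.12 (truth 0.10),
each with its delta-method standard error; `p_value` is the boundary-mixture
LRT against dropping that component (the genic signal is decisive at
p ≈ 6e-5, the weaker intergenic one marginal at p ≈ 0.04, as expected at
n = 800).

The twin arm of the same configuration (134 MZ / 99 DZ pairs generated under
ACE = (0.60, 0.02, 0.38)):

```r
tw <- simulate_twins(cfg)
fit_ace(tw)
#> <ace_fit> a2 = 0.627, c2 = 0.000, e2 = 0.373 (134 MZ / 99 DZ pairs)
#>   implied rMZ = 0.627, rDZ = 0.313 | -2logL = 1232.13
falconer(0.62, 0.32)
#>   a2   c2   e2
#> 0.60 0.02 0.38
```

At this design size a single replicate estimates a² with a standard error
around 0.15, so 0.63 against a truth of 0.60 is typical; the shared
environment collapses to its boundary.

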