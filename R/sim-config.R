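#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator: cohort and marker
#' dimensions, the blockwise LD model, annotation geometry, the genetic
#' architecture of the phenotype, planted cryptic relatedness, and the twin
#' design. The defaults describe the study conditions the package's validation
#' suite runs under: a polygenic trait with total SNP heritability 0.45, an
#' ACE twin model implying MZ/DZ correlations of 0.62/0.32, and LD blocks of
#' 20 common SNPs with adjacent-haplotype correlation 0.5.
#'
#' @param n_subjects Number of unrelated subjects to simulate.
#' @param n_snps Number of autosomal SNPs.
#' @param block_size SNPs per LD block; haplotypes are independent across
#'   blocks.
#' @param ld_rho Lag-1 allele correlation of the within-block Markov chain,
#'   in `[0, 1)`. When positive, all SNPs in a block share one allele
#'   frequency drawn from `maf_range` (the target correlation is otherwise
#'   unattainable between frequency-mismatched loci); when zero, frequencies
#'   are drawn per SNP.
#' @param maf_range Length-2 numeric, lower/upper bounds of the uniform
#'   allele-frequency draw; must lie in `(0, 0.5]`.
#' @param frac_genic Fraction of the SNP span covered by the flanked genic
#'   annotation (gene spans plus `flank_bp` on each side).
#' @param flank_bp Flank applied to gene spans, both for coverage targeting in
#'   [simulate_annotation()] and as the default in [annotate_genic()].
#' @param causal_fraction_by_category Named numeric: fraction of each
#'   category's SNPs that carry effects.
#' @param h2_by_category Named numeric: per-category variance proportions;
#'   their sum must not exceed `h2_total`. Empty means a single genome-wide
#'   category.
#' @param h2_total Total SNP heritability of the simulated trait, in `[0, 1)`.
#' @param covariate_effects Logical; include age (nonlinear), sex and cohort
#'   fixed effects in the phenotype.
#' @param rescale_exact Logical; rescale realized genetic values so the
#'   realized genetic variance equals `h2_total` exactly (sharpens
#'   parameter-recovery tests). Set `FALSE` for expected-value scaling.
#' @param missing_score_fraction Fraction of SNPs whose conservation score is
#'   missing (emulating unscored positions that are dropped downstream).
#' @param n_mz_pairs,n_dz_pairs Twin-pair counts for [simulate_twins()].
#' @param ace_true Length-3 numeric `(a2, c2, e2)` summing to 1.
#' @param n_related_pairs Number of related pairs planted by
#'   [plant_relatedness()].
#' @param related_kinship Target GRM entry for planted pairs, in `(0, 1]`.
#' @param spacing_bp Base-pair spacing between consecutive SNPs (positions are
#'   1-based on one synthetic chromosome).
#' @param chrom Chromosome label used in the synthetic map.
#' @param seed Integer seed; identical seeds give byte-identical output from
#'   every simulator. `NULL` uses the session RNG stream.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_subjects = 50, n_snps = 200, seed = 1)
#' cfg$h2_total
#' @export
sim_config <- function(n_subjects = 1000,
                       n_snps = 5000,
                       block_size = 20,
                       ld_rho = 0.5,
                       maf_range = c(0.05, 0.5),
                       frac_genic = 0.5,
                       flank_bp = 20000,
                       causal_fraction_by_category = NULL,
                       h2_by_category = NULL,
                       h2_total = 0.45,
                       covariate_effects = TRUE,
                       rescale_exact = TRUE,
                       missing_score_fraction = 0.02,
                       n_mz_pairs = 134,
                       n_dz_pairs = 99,
                       ace_true = c(0.60, 0.02, 0.38),
                       n_related_pairs = 0,
                       related_kinship = 0.125,
                       spacing_bp = 1000,
                       chrom = "1",
                       seed = NULL) {
  cfg <- structure(
    list(
      n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
      block_size = as.integer(block_size), ld_rho = ld_rho,
      maf_range = maf_range, frac_genic = frac_genic, flank_bp = flank_bp,
      causal_fraction_by_category = causal_fraction_by_category,
      h2_by_category = h2_by_category, h2_total = h2_total,
      covariate_effects = isTRUE(covariate_effects),
      rescale_exact = isTRUE(rescale_exact),
      missing_score_fraction = missing_score_fraction,
      n_mz_pairs = as.integer(n_mz_pairs), n_dz_pairs = as.integer(n_dz_pairs),
      ace_true = ace_true, n_related_pairs = as.integer(n_related_pairs),
      related_kinship = related_kinship, spacing_bp = as.integer(spacing_bp),
      chrom = as.character(chrom),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_subjects < 1L || cfg$n_snps < 1L || cfg$block_size < 1L) {
    abort("n_subjects, n_snps and block_size must be positive.",
          class = "heritkit_config_error")
  }
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) {
    abort("ld_rho must lie in [0, 1).", class = "heritkit_config_error")
  }
  mr <- cfg$maf_range
  if (length(mr) != 2 || mr[1] > mr[2] || mr[1] <= 0 || mr[2] > 0.5) {
    abort("maf_range must be (low, high) within (0, 0.5].",
          class = "heritkit_config_error")
  }
  if (cfg$frac_genic < 0 || cfg$frac_genic > 1) {
    abort("frac_genic must lie in [0, 1].", class = "heritkit_config_error")
  }
  if (cfg$h2_total < 0 || cfg$h2_total >= 1) {
    abort("h2_total must lie in [0, 1).", class = "heritkit_config_error")
  }
  h2c <- cfg$h2_by_category
  if (!is.null(h2c)) {
    if (is.null(names(h2c)) || any(names(h2c) == "")) {
      abort("h2_by_category must be a named numeric vector.",
            class = "heritkit_config_error")
    }
    if (any(h2c < 0 | h2c > 1) || sum(h2c) > cfg$h2_total + 1e-12) {
      abort("h2_by_category entries must lie in [0,1] and sum to at most h2_total.",
            class = "heritkit_config_error")
    }
  }
  if (abs(sum(cfg$ace_true) - 1) > 1e-12 || any(cfg$ace_true < 0)) {
    abort("ace_true must be nonnegative and sum to 1 (within 1e-12).",
          class = "heritkit_config_error")
  }
  if (cfg$n_related_pairs > cfg$n_subjects %/% 2L) {
    abort("n_related_pairs cannot exceed n_subjects / 2.",
          class = "heritkit_config_error")
  }
  if (cfg$n_related_pairs > 0 &&
      (cfg$related_kinship <= 0 || cfg$related_kinship > 1)) {
    abort("related_kinship must lie in (0, 1].", class = "heritkit_config_error")
  }
  if (cfg$missing_score_fraction < 0 || cfg$missing_score_fraction > 1) {
    abort("missing_score_fraction must lie in [0, 1].",
          class = "heritkit_config_error")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  subjects: %d   SNPs: %d (blocks of %d, rho = %.2f)\n",
              x$n_subjects, x$n_snps, x$block_size, x$ld_rho))
  cat(sprintf("  h2_total: %.2f   genic fraction: %.2f\n",
              x$h2_total, x$frac_genic))
  cat(sprintf("  twins: %d MZ / %d DZ, ACE = (%.2f, %.2f, %.2f)\n",
              x$n_mz_pairs, x$n_dz_pairs,
              x$ace_true[1], x$ace_true[2], x$ace_true[3]))
  if (x$n_related_pairs > 0) {
    cat(sprintf("  planted related pairs: %d at kinship %.3f\n",
                x$n_related_pairs, x$related_kinship))
  }
  invisible(x)
}

# Run `expr` under a locally-seeded RNG stream, restoring session RNG state.
# `offset` decorrelates stages that share one config seed.
with_sim_seed <- function(seed, offset, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  force(expr)
}
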