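test_that("blockwise Markov haplotypes attain the target adjacent LD", {
  cfg <- sim_config(n_subjects = 5000, n_snps = 100, block_size = 10,
                    ld_rho = 0.8, seed = 11)
  g <- simulate_genotypes(cfg)
  x <- g$dosages
  r <- vapply(seq_len(ncol(x) - 1),
              function(j) cor(x[, j], x[, j + 1]), numeric(1))
  same_block <- g$snp_map$block[-nrow(g$snp_map)] == g$snp_map$block[-1]
  expect_lt(abs(mean(r[same_block]) - 0.8), 0.05)
  expect_lt(abs(mean(r[!same_block])), 0.05)
})

test_that("uncorrelated SNPs show no residual correlation", {
  cfg <- sim_config(n_subjects = 10000, n_snps = 2, block_size = 1,
                    ld_rho = 0, seed = 12)
  g <- simulate_genotypes(cfg)
  expect_lt(abs(cor(g$dosages[, 1], g$dosages[, 2])), 0.03)
})

test_that("empirical MAF tracks the generating frequency", {
  cfg <- sim_config(n_subjects = 2000, n_snps = 40, maf_range = c(0.5, 0.5),
                    seed = 13)
  g <- simulate_genotypes(cfg)
  maf <- pmin(colMeans(g$dosages) / 2, 1 - colMeans(g$dosages) / 2)
  expect_true(all(maf > 0.45 & maf <= 0.5))

  cfg2 <- sim_config(n_subjects = 1500, n_snps = 200, ld_rho = 0.4, seed = 14)
  g2 <- simulate_genotypes(cfg2)
  phat <- colMeans(g2$dosages) / 2
  p <- g2$snp_map$freq
  se <- sqrt(p * (1 - p) / (2 * nrow(g2$dosages)))
  expect_true(all(abs(phat - p) < 4 * se))
})

test_that("simulators are byte-identical under a fixed seed", {
  cfg <- sim_config(n_subjects = 60, n_snps = 120, n_related_pairs = 3,
                    related_kinship = 0.25, seed = 99)
  expect_identical(simulate_genotypes(cfg), simulate_genotypes(cfg))
  g <- simulate_genotypes(cfg)
  expect_identical(simulate_annotation(g$snp_map, cfg),
                   simulate_annotation(g$snp_map, cfg))
  expect_identical(simulate_phenotype(g, config = cfg),
                   simulate_phenotype(g, config = cfg))
  expect_identical(simulate_twins(cfg), simulate_twins(cfg))
  expect_identical(plant_relatedness(g, cfg), plant_relatedness(g, cfg))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_subjects = 0), class = "heritkit_config_error")
  expect_error(sim_config(ld_rho = 1), class = "heritkit_config_error")
  expect_error(sim_config(maf_range = c(0, 0.6)),
               class = "heritkit_config_error")
  expect_error(sim_config(ace_true = c(0.5, 0.5, 0.1)),
               class = "heritkit_config_error")
  expect_error(sim_config(h2_by_category = c(a = 0.4), h2_total = 0.3),
               class = "heritkit_config_error")
})

test_that("null-heritability phenotypes carry no genetic signal", {
  cfg <- sim_config(n_subjects = 500, n_snps = 400, h2_total = 0, seed = 21)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, config = cfg)
  expect_true(all(ph$phenotypes$g_true == 0))
  expect_equal(ph$h2_realized, 0)
})

test_that("realized genetic variance hits the target exactly after rescaling", {
  cfg <- sim_config(n_subjects = 2000, n_snps = 1000, h2_total = 0.45,
                    covariate_effects = FALSE, seed = 22)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, config = cfg)
  expect_equal(ph$h2_realized, 0.45, tolerance = 1e-10)
  n <- nrow(ph$phenotypes)
  ratio <- (var(ph$phenotypes$g_true) * (n - 1) / n) / var(ph$phenotypes$y)
  expect_gt(ratio, 0.40)
  expect_lt(ratio, 0.50)
  # unit phenotype variance up to Monte-Carlo error with covariates off
  expect_lt(abs(var(ph$phenotypes$y) - 1), 0.1)
})

test_that("category-specific enrichment realizes the requested ratio", {
  cfg <- sim_config(n_subjects = 800, n_snps = 1000,
                    h2_by_category = c(genic = 0.30, intergenic = 0.10),
                    h2_total = 0.40, seed = 23)
  g <- simulate_genotypes(cfg)
  ann <- simulate_annotation(g$snp_map, cfg)
  track <- annotate_genic(g$snp_map, ann$genes)
  ph <- simulate_phenotype(g, track[, c("snp_id", "category")], cfg)
  v <- apply(ph$g_by_category, 2, var)
  expect_lt(abs(v[["genic"]] / v[["intergenic"]] - 3), 0.3)
})

test_that("phenotype simulation rejects empty causal categories", {
  cfg <- sim_config(n_subjects = 50, n_snps = 100,
                    h2_by_category = c(rare = 0.2), h2_total = 0.2,
                    causal_fraction_by_category = c(rare = 0.001), seed = 1)
  g <- simulate_genotypes(cfg)
  ann <- tibble::tibble(snp_id = g$snp_map$id,
                        category = rep(c("rare", "other"), each = 50))
  expect_error(simulate_phenotype(g, ann, cfg),
               class = "heritkit_config_error")
})

test_that("twin pairs reproduce the ACE-implied correlations", {
  r <- twin_correlations(simulate_twins(
    sim_config(n_mz_pairs = 2000, n_dz_pairs = 2000,
               ace_true = c(1, 0, 0), seed = 31)))
  expect_gt(r$r_mz, 0.98)

  r2 <- twin_correlations(simulate_twins(
    sim_config(n_mz_pairs = 5000, n_dz_pairs = 5000,
               ace_true = c(0.60, 0.02, 0.38), seed = 32)))
  expect_lt(abs(r2$r_mz - 0.62), 0.02)
  expect_lt(abs(r2$r_dz - 0.32), 0.02)

  r3 <- twin_correlations(simulate_twins(
    sim_config(n_mz_pairs = 2000, n_dz_pairs = 2000,
               ace_true = c(0, 0, 1), seed = 33)))
  expect_lt(abs(r3$r_mz), 0.05)
  expect_lt(abs(r3$r_dz), 0.05)
})

test_that("planted relatedness lands at the target GRM entry", {
  # sibling-like sharing
  cfg <- sim_config(n_subjects = 60, n_snps = 5000, ld_rho = 0,
                    block_size = 20, n_related_pairs = 3,
                    related_kinship = 0.5, maf_range = c(0.2, 0.5),
                    seed = 41)
  g <- plant_relatedness(simulate_genotypes(cfg), cfg)
  grm <- compute_grm(g)
  pairs <- attr(g, "planted_pairs")
  planted <- mapply(function(i, j) grm$values[i, j], pairs$first, pairs$second)
  expect_true(all(planted > 0.35 & planted < 0.65))

  # weak relatedness straddling the 0.025 pruning threshold
  # a larger cohort keeps the -1/(n-1) in-sample-centring bias of the GRM
  # off-diagonal well below the planted signal
  cfg2 <- sim_config(n_subjects = 300, n_snps = 20000, ld_rho = 0,
                     n_related_pairs = 3, related_kinship = 0.05,
                     maf_range = c(0.2, 0.5), seed = 42)
  g2 <- plant_relatedness(simulate_genotypes(cfg2), cfg2)
  grm2 <- compute_grm(g2)
  pairs2 <- attr(g2, "planted_pairs")
  planted2 <- mapply(function(i, j) grm2$values[i, j],
                     pairs2$first, pairs2$second)
  expect_true(all(planted2 > 0.02 & planted2 < 0.08))

  # zero pairs is the identity
  cfg3 <- sim_config(n_subjects = 20, n_snps = 100, n_related_pairs = 0,
                     seed = 43)
  g3 <- simulate_genotypes(cfg3)
  expect_identical(plant_relatedness(g3, cfg3), g3)
})

test_that("annotation simulation honours coverage and missingness", {
  cfg0 <- sim_config(n_subjects = 10, n_snps = 500, frac_genic = 0, seed = 51)
  g <- simulate_genotypes(cfg0)
  ann0 <- simulate_annotation(g$snp_map, cfg0)
  expect_equal(nrow(ann0$genes), 0)
  expect_true(all(annotate_genic(g$snp_map, ann0$genes)$category ==
                    "intergenic"))

  cfg1 <- sim_config(n_subjects = 10, n_snps = 500, frac_genic = 1, seed = 52)
  ann1 <- simulate_annotation(g$snp_map, cfg1)
  expect_true(all(annotate_genic(g$snp_map, ann1$genes)$category == "genic"))

  cfg2 <- sim_config(n_subjects = 10, n_snps = 10000,
                     missing_score_fraction = 0.02, seed = 53)
  g2 <- simulate_genotypes(cfg2)
  ann2 <- simulate_annotation(g2$snp_map, cfg2)
  n_miss <- sum(is.na(ann2$scores$score))
  expect_true(abs(n_miss - 200) <= 30)

  cfg3 <- sim_config(n_subjects = 10, n_snps = 10000,
                     missing_score_fraction = 0, seed = 54)
  ann3 <- simulate_annotation(g2$snp_map, cfg3)
  expect_true(all(!is.na(ann3$scores$score)))
  expect_true(all(ann3$scores$score >= 0 & ann3$scores$score <= 1))
})
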