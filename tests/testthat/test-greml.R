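test_that("with an identity GRM the REML criterion collapses to iid normal", {
  set.seed(71)
  n <- 5
  y <- rnorm(n)
  X <- matrix(1, n, 1)
  s <- c(0.4, 0.6)  # total iid variance 1.0
  ll <- reml_loglik(y, X, diag(1, n), s)
  tot <- sum(s)
  rss <- sum((y - mean(y))^2)
  closed <- -0.5 * ((n - 1) * log(tot) + rss / tot + (n - 1) * log(2 * pi))
  expect_equal(ll, closed, tolerance = 1e-10)
})

test_that("the restricted likelihood is Gaussian scale-equivariant", {
  set.seed(72)
  n <- 40; p <- 3
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  g <- compute_grm(toy_genotypes(random_dosages(n, 100, seed = 72)))$values
  y <- rnorm(n)
  s <- c(0.3, 0.7)
  shift <- reml_loglik(2 * y, X, g, 4 * s) - reml_loglik(y, X, g, s)
  expect_equal(shift, -(n - p) * log(2), tolerance = 1e-8)
})

test_that("reml_loglik equals the dense error-contrast evaluation", {
  set.seed(73)
  n <- 60
  X <- cbind(1, rnorm(n))
  g <- compute_grm(toy_genotypes(random_dosages(n, 150, seed = 73)))$values
  y <- rnorm(n)
  for (i in 1:5) {
    s <- runif(2, 0.2, 2)
    v <- s[1] * g + s[2] * diag(1, n)
    expect_equal(reml_loglik(y, X, g, s), contrast_reml_loglik(y, X, v),
                 tolerance = 1e-8)
  }
})

test_that("spectral and dense AI-REML backends agree everywhere", {
  set.seed(74)
  n <- 100
  g <- compute_grm(toy_genotypes(random_dosages(n, 300, seed = 74)))$values
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  spec <- heritkit:::make_spectral_backend(y, X, g)
  dense <- heritkit:::make_dense_backend(y, X, list(g))
  for (i in 1:4) {
    s <- runif(2, 0.2, 1.5)
    a <- spec(s); b <- dense(s)
    expect_equal(a$loglik, b$loglik, tolerance = 1e-8)
    expect_equal(a$q, b$q, tolerance = 1e-6)
    expect_equal(a$t, b$t, tolerance = 1e-6)
    expect_equal(a$ai, b$ai, tolerance = 1e-6)
  }
})

test_that("a moderate simulation recovers its generating heritability", {
  cfg <- sim_config(n_subjects = 600, n_snps = 2000, h2_total = 0.45,
                    covariate_effects = FALSE, seed = 75)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, config = cfg)
  grm <- compute_grm(g)
  fit <- reml_fit(ph$phenotypes$y, matrix(1, 600, 1), grm$values)
  h2 <- fit$components$prop[1]
  se <- fit$components$prop_se[1]
  expect_true(fit$converged)
  expect_lt(abs(h2 - 0.45), 2.5 * se)
  # scale invariance of the proportion
  fit2 <- reml_fit(3 * ph$phenotypes$y, matrix(1, 600, 1), grm$values)
  expect_equal(fit2$components$prop[1], h2, tolerance = 1e-6)
})

test_that("permuted phenotypes drive the estimate to the boundary", {
  cfg <- sim_config(n_subjects = 400, n_snps = 1500, h2_total = 0.45,
                    covariate_effects = FALSE, seed = 76)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, config = cfg)
  grm <- compute_grm(g)
  set.seed(761)
  h2_perm <- vapply(1:5, function(i) {
    yp <- sample(ph$phenotypes$y)
    reml_fit(yp, matrix(1, 400, 1), grm$values)$components$prop[1]
  }, numeric(1))
  expect_lt(mean(h2_perm), 0.15)
})

test_that("the boundary-mixture LRT maps statistics to tail probabilities", {
  z <- lrt(10, 10)
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 0.5)

  # 2.706 is the classic one-sided 5% point of the mixture null
  expect_lt(abs(lrt(2.706 / 2, 0)$p_value - 0.05), 1e-3)
  # 7.10 lands at ~0.004, the Bonferroni threshold for 12 phenotypes
  p <- lrt(7.10 / 2, 0)$p_value
  expect_gt(p, 0.0035); expect_lt(p, 0.0045)

  expect_error(lrt(0, 1), class = "heritkit_fit_error")
  expect_warning(lrt(5, 0, df_dropped = 2), regexp = "conservative")
})

test_that("a degenerate one-category partition reproduces the single fit", {
  cfg <- sim_config(n_subjects = 250, n_snps = 800, h2_total = 0.4,
                    covariate_effects = FALSE, seed = 77)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, config = cfg)
  pheno <- ph$phenotypes[, c("fid", "iid", "y")]
  single <- estimate_h2(g, pheno, n_pcs = 4)
  part <- list(all = g$snp_map$id)
  partitioned <- estimate_h2(g, pheno, partition = part, n_pcs = 4)
  expect_equal(partitioned$prop[1], single$prop[1], tolerance = 1e-6)
  expect_equal(partitioned$loglik[1], single$loglik[1], tolerance = 1e-6)
})

test_that("estimate_h2 aligns subjects and validates inputs", {
  cfg <- sim_config(n_subjects = 60, n_snps = 200, seed = 78)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, config = cfg)$phenotypes
  expect_error(estimate_h2(g, ph[-1, c("fid", "iid", "y")]),
               class = "heritkit_format_error")
  # shuffled phenotype rows are re-aligned by IID before fitting
  shuffled <- ph[sample(nrow(ph)), c("fid", "iid", "y")]
  a <- estimate_h2(g, ph[, c("fid", "iid", "y")], n_pcs = 2)
  b <- estimate_h2(g, shuffled, n_pcs = 2)
  expect_equal(a$prop, b$prop, tolerance = 1e-10)
})

test_that("tidy and glance expose the fit in broom convention", {
  set.seed(79)
  n <- 80
  g <- compute_grm(toy_genotypes(random_dosages(n, 200, seed = 79)))$values
  fit <- reml_fit(rnorm(n), matrix(1, n, 1), g)
  td <- tidy(fit)
  expect_named(td, c("component", "sigma2", "se", "prop", "prop_se"))
  expect_equal(sum(td$prop), 1, tolerance = 1e-8)
  gl <- glance(fit)
  expect_equal(gl$n, n)
  expect_true(is.finite(gl$loglik))
})
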