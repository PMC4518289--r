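test_that("the off-diagonal estimator matches hand evaluation", {
  # two subjects, one SNP, dosages (0, 2), p = 0.5:
  # (0 - 1)(2 - 1) / (2 * 0.25) = -2
  g <- toy_genotypes(matrix(c(0, 2), 2, 1))
  grm <- compute_grm(g)
  expect_equal(grm$values[1, 2], -2)
})

test_that("identical genotype rows give A_jk equal to the diagonal", {
  x <- random_dosages(8, 150, seed = 11, maf = c(0.25, 0.5))
  x[2, ] <- x[1, ]
  f <- colMeans(x) / 2
  x <- x[, f > 0 & f < 1, drop = FALSE]
  g <- toy_genotypes(x)
  # exact identity under the squared-standardized diagonal
  grm_s <- compute_grm(g, diagonal = "simple")
  expect_equal(grm_s$values[1, 2], grm_s$values[1, 1], tolerance = 1e-12)
  # the inbreeding-adjusted diagonal agrees in expectation, not per subject
  grm_g <- compute_grm(g)
  expect_lt(abs(grm_g$values[1, 1] - grm_g$values[1, 2]), 0.3)
  expect_false(isTRUE(all.equal(grm_g$values[1, 1], grm_s$values[1, 1],
                                tolerance = 1e-12)))
})

test_that("vectorized GRM equals the brute-force double loop", {
  x <- random_dosages(30, 120, seed = 12)
  x[sample(length(x), 40)] <- NA  # exercise pairwise SNP counting too
  f <- colMeans(x, na.rm = TRUE) / 2
  x <- x[, f > 0 & f < 1, drop = FALSE]
  grm <- compute_grm(toy_genotypes(x))
  expect_lt(max(abs(grm$values - brute_force_grm(x))), 1e-12)
})

test_that("GRM summaries behave on unrelated synthetic data", {
  cfg <- sim_config(n_subjects = 150, n_snps = 2000, ld_rho = 0, seed = 13)
  grm <- compute_grm(simulate_genotypes(cfg))
  expect_lt(max(abs(grm$values - t(grm$values))), 1e-12)
  expect_gt(mean(diag(grm$values)), 0.8)
  expect_lt(mean(diag(grm$values)), 1.2)
  off <- grm$values[upper.tri(grm$values)]
  expect_lt(abs(mean(off)), 4 / sqrt(150 * 2000))
  expect_true(all(grm$pair_snp_counts >= 1))
})

test_that("monomorphic SNPs are refused by name", {
  x <- random_dosages(10, 5, seed = 14)
  x[, 3] <- 2
  expect_error(compute_grm(toy_genotypes(x)), regexp = "s003",
               class = "heritkit_monomorphic_error")
})

test_that("relatedness pruning removes one member per isolated pair", {
  a <- diag(1, 4)
  ids <- paste0("I", 1:4)
  dimnames(a) <- list(ids, ids)
  kept <- prune_related(a, 0.1)
  expect_equal(kept, ids, ignore_attr = TRUE)

  a[1, 2] <- a[2, 1] <- 0.3
  kept2 <- prune_related(a, 0.1)
  expect_length(setdiff(ids, kept2), 1)
  expect_length(intersect(c("I1", "I2"), kept2), 1)
})

test_that("greedy pruning removes the hub of a relatedness triangle", {
  ids <- c("A", "B", "C")
  a <- diag(1, 3); dimnames(a) <- list(ids, ids)
  a["A", "B"] <- a["B", "A"] <- 0.2
  a["B", "C"] <- a["C", "B"] <- 0.2
  a["A", "C"] <- a["C", "A"] <- 0.01
  kept <- prune_related(a, 0.1)
  expect_equal(sort(kept), c("A", "C"))
})

test_that("greedy pruning is near-optimal and pair-free on small instances", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(6:12, 1)
    a <- matrix(0, n, n)
    hot <- which(upper.tri(a) & matrix(runif(n * n) < 0.25, n, n))
    a[hot] <- runif(length(hot), 0.05, 0.5)
    a <- a + t(a); diag(a) <- 1
    rownames(a) <- colnames(a) <- paste0("I", seq_len(n))
    kept <- prune_related(a, 0.025)
    idx <- match(kept, rownames(a))
    sub <- a[idx, idx, drop = FALSE]; diag(sub) <- 0
    expect_true(all(sub <= 0.025))
    opt <- exhaustive_prune_optimum(a, 0.025)
    expect_gte(length(kept), opt - 1)
  }
})

test_that("GRM principal components satisfy the eigen definition", {
  x <- random_dosages(40, 300, seed = 15)
  grm <- compute_grm(toy_genotypes(x))
  pcs <- grm_pca(grm, k = 5)
  ev <- attr(pcs, "eigenvalues")
  expect_true(all(diff(ev) <= 1e-10))
  for (j in 1:5) {
    resid <- grm$values %*% pcs[, j] - ev[j] * pcs[, j]
    expect_lt(sqrt(sum(resid^2)), 1e-8)
    expect_equal(sum(pcs[, j]^2), 1, tolerance = 1e-10)
    expect_gt(pcs[which.max(abs(pcs[, j])), j], 0)  # sign convention
  }
  expect_error(grm_pca(grm, k = 40), class = "heritkit_config_error")
})

test_that("the identity GRM yields a flat unit spectrum", {
  ev <- attr(grm_pca(diag(1, 12), k = 4), "eigenvalues")
  expect_equal(ev, rep(1, 4), tolerance = 1e-12)
})

test_that("the leading principal component separates planted populations", {
  set.seed(16)
  n_half <- 60; m <- 400
  p1 <- runif(m, 0.1, 0.5)
  shift <- sample(c(-0.25, 0.25), m, replace = TRUE)
  p2 <- pmin(0.95, pmax(0.05, p1 + shift))
  x <- rbind(sapply(p1, function(p) rbinom(n_half, 2, p)),
             sapply(p2, function(p) rbinom(n_half, 2, p)))
  f <- colMeans(x) / 2
  x <- x[, f > 0 & f < 1]
  pcs <- grm_pca(compute_grm(toy_genotypes(x)), k = 2)
  pop <- rep(c(0, 1), each = n_half)
  expect_gt(abs(cor(pcs[, 1], pop)), 0.9)
})
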