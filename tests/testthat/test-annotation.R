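test_that("genic labelling follows the closed-flank boundary arithmetic", {
  # BED [99999, 200000) is 1-based [100000, 200000]; with 20 kb flanks the
  # genic window is [80000, 220000]
  genes <- tibble::tibble(chrom = "1", start = 99999L, end = 200000L,
                          name = "g1")
  map <- tibble::tibble(id = c("a", "b", "c", "d"), chrom = "1",
                        pos = c(79999L, 80000L, 220000L, 220001L))
  track <- annotate_genic(map, genes, flank_bp = 20000)
  expect_equal(track$category, c("intergenic", "genic", "genic", "intergenic"))
})

test_that("an empty gene table labels everything intergenic", {
  map <- tibble::tibble(id = letters[1:3], chrom = "1",
                        pos = c(1L, 100L, 200L))
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character())
  expect_true(all(annotate_genic(map, empty)$category == "intergenic"))
})

test_that("chromosome mismatches raise a named error", {
  map <- tibble::tibble(id = "a", chrom = "1", pos = 10L)
  genes <- tibble::tibble(chrom = "2", start = 1L, end = 100L, name = "g")
  expect_error(annotate_genic(map, genes), regexp = "chromosome",
               class = "heritkit_format_error")
  expect_error(annotate_genic(map,
                              tibble::tibble(chrom = "1", start = 10L,
                                             end = 5L, name = "g")),
               class = "heritkit_format_error")
})

test_that("genic labels agree with a brute-force interval scan", {
  cfg <- sim_config(n_subjects = 10, n_snps = 4000, frac_genic = 0.4,
                    seed = 61)
  g <- simulate_genotypes(cfg)
  ann <- simulate_annotation(g$snp_map, cfg)
  track <- annotate_genic(g$snp_map, ann$genes, flank_bp = 20000)
  brute <- vapply(g$snp_map$pos, function(pos) {
    any(pos >= ann$genes$start + 1 - 20000 & pos <= ann$genes$end + 20000)
  }, logical(1))
  expect_equal(track$category == "genic", brute)
})

test_that("simulated gene coverage matches the requested genic fraction", {
  cfg <- sim_config(n_subjects = 10, n_snps = 10000, frac_genic = 0.5,
                    seed = 62)
  g <- simulate_genotypes(cfg)
  ann <- simulate_annotation(g$snp_map, cfg)
  frac <- mean(annotate_genic(g$snp_map, ann$genes)$category == "genic")
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)
})

test_that("windowed r2 matches brute-force correlation", {
  x <- random_dosages(50, 3, seed = 63)
  g <- toy_genotypes(x)
  ld <- compute_ld_matrix(g, window_bp = 1e6)
  r2 <- as.matrix(ld$r2)
  expect_equal(diag(r2), rep(1, 3))
  for (a in 1:2) for (b in (a + 1):3) {
    expect_equal(r2[a, b], cor(x[, a], x[, b])^2, tolerance = 1e-12)
  }
  expect_true(all(r2[upper.tri(r2)] < 0.2))  # independent draws at n = 50
})

test_that("duplicated SNP columns are in perfect LD", {
  x <- random_dosages(30, 2, seed = 64)
  x <- cbind(x, x[, 1])
  ld <- compute_ld_matrix(toy_genotypes(x), window_bp = 1e6)
  expect_equal(as.matrix(ld$r2)[1, 3], 1, tolerance = 1e-12)
})

test_that("the base-pair window and variance guard are enforced", {
  x <- random_dosages(20, 4, seed = 65)
  g <- toy_genotypes(x, spacing = 1000L)
  ld <- compute_ld_matrix(g, window_bp = 1500)
  r2 <- as.matrix(ld$r2)
  expect_equal(r2[1, 3], 0)  # 2 kb apart: outside the window, not stored
  expect_true(r2[1, 2] > 0 || x[1, 1] == x[1, 2])

  x[, 2] <- 1
  expect_error(compute_ld_matrix(toy_genotypes(x)), regexp = "s002",
               class = "heritkit_monomorphic_error")
})

test_that("LD weighting reproduces the hand-computed weighted average", {
  r2 <- matrix(c(1, 0.5, 0,
                 0.5, 1, 0.5,
                 0, 0.5, 1), 3, 3)
  ld <- manual_ld_matrix(r2, c("a", "b", "c"))
  track <- tibble::tibble(snp_id = c("a", "b", "c"), score = c(1, 0, 0))
  w <- ld_weight_scores(ld, track)
  expect_equal(w$weighted, c(2 / 3, 0.25, 0), tolerance = 1e-12)
})

test_that("LD weighting is a convex, constant-preserving smoother", {
  cfg <- sim_config(n_subjects = 100, n_snps = 400, seed = 66,
                    missing_score_fraction = 0.05)
  g <- simulate_genotypes(cfg)
  ann <- simulate_annotation(g$snp_map, cfg)
  ld <- compute_ld_matrix(g, window_bp = 30000)
  track <- tibble::tibble(snp_id = g$snp_map$id, score = ann$scores$score)
  w <- ld_weight_scores(ld, track)
  scored <- !is.na(w$weighted)
  expect_true(all(w$weighted[scored] >= min(track$score, na.rm = TRUE) - 1e-12))
  expect_true(all(w$weighted[scored] <= max(track$score, na.rm = TRUE) + 1e-12))

  const <- tibble::tibble(snp_id = g$snp_map$id,
                          score = rep(0.37, nrow(g$snp_map)))
  expect_equal(ld_weight_scores(ld, const)$weighted,
               rep(0.37, nrow(g$snp_map)), tolerance = 1e-12)

  ident <- manual_ld_matrix(diag(1, 5), paste0("s", 1:5))
  tr <- tibble::tibble(snp_id = paste0("s", 1:5),
                       score = c(0.1, NA, 0.5, 0.9, 0.3))
  w2 <- ld_weight_scores(ident, tr)
  expect_equal(w2$weighted, tr$score)  # identity LD: weighted = raw, NA kept
})

test_that("median split balances scored SNPs and applies the tie rule", {
  tr <- tibble::tibble(snp_id = paste0("s", 1:4),
                       score = c(0.1, 0.2, 0.3, 0.4))
  sp <- median_split(tr)
  expect_equal(sp$category, c("low", "low", "high", "high"))

  odd <- tibble::tibble(snp_id = paste0("s", 1:3), score = c(0.1, 0.2, 0.3))
  sp2 <- median_split(odd)
  expect_equal(sp2$category, c("low", "low", "high"))  # median goes low

  set.seed(67)
  big <- tibble::tibble(snp_id = seq_len(10000),
                        score = rbeta(10000, 2, 5))
  sp3 <- median_split(big)
  expect_lte(abs(sum(sp3$category == "low") - sum(sp3$category == "high")), 1)

  expect_error(median_split(tibble::tibble(snp_id = 1:3,
                                           score = rep(0.5, 3))),
               class = "heritkit_degenerate_error")
})

test_that("score correlation returns r and shared variance", {
  tr <- tibble::tibble(snp_id = 1:5, score = c(0.2, 0.4, 0.1, 0.9, 0.5))
  self <- score_correlation(tr, tr)
  expect_equal(self$r, 1)
  expect_equal(self$r_squared, 1)

  anti <- score_correlation(c(0, 1, 2), c(2, 1, 0))
  expect_equal(anti$r, -1)

  expect_error(score_correlation(c(1, 1, 1), c(0, 1, 2)),
               class = "heritkit_degenerate_error")
})

test_that("partitions are disjoint, complete and validated", {
  tr <- tibble::tibble(snp_id = paste0("s", 1:6),
                       category = c("genic", "genic", "intergenic",
                                    "intergenic", "intergenic", NA))
  part <- build_partition(tr)
  expect_equal(sort(names(part)), c("genic", "intergenic"))
  expect_equal(sum(lengths(part)), 5)  # NA-category SNP dropped
  expect_length(intersect(part$genic, part$intergenic), 0)

  dup <- tibble::tibble(snp_id = c("a", "a"), category = c("x", "y"))
  expect_error(build_partition(dup), class = "heritkit_format_error")
  expect_error(build_partition(tibble::tibble(snp_id = "a",
                                              category = NA_character_)),
               class = "heritkit_format_error")
})
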