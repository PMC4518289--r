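#' Genotype quality control
#'
#' Applies, in this fixed order: (1) removal of samples missing more than
#' `miss_max` of their SNPs (strict `>`); (2) removal of SNPs with minor
#' allele frequency below `maf_min` (strict `<`); (3) removal of SNPs failing
#' a 1-df chi-square test of Hardy-Weinberg equilibrium at `hwe_alpha`
#' (strict `<`); (4) removal of samples whose heterozygosity rate lies more
#' than `het_sd` standard deviations from the sample mean. MAF uses mean
#' dosage / 2 (so fractional imputed dosages contribute); HWE and
#' heterozygosity use hard calls only.
#'
#' A single call runs each rule once. Because the heterozygosity pass is
#' recomputed on the retained set, re-running `qc_filter()` on its own output
#' can remove further samples; iterating reaches a fixpoint quickly (see
#' [qc_fixpoint()]).
#'
#' @param genotypes A [genotype_matrix()].
#' @param miss_max Maximum tolerated per-sample missingness.
#' @param maf_min Minimum minor allele frequency.
#' @param hwe_alpha Hardy-Weinberg chi-square p-value threshold.
#' @param het_sd Heterozygosity outlier cutoff in standard deviations.
#' @return List of class `qc_result`: `genotypes` (filtered), `report`
#'   (tibble: `unit` sample/snp, `id`, `reason`, `value`), `thresholds`,
#'   `counts` (before/after).
#' @examples
#' g <- simulate_genotypes(sim_config(n_subjects = 100, n_snps = 300, seed = 1))
#' qc <- qc_filter(g)
#' qc$counts
#' @export
qc_filter <- function(genotypes, miss_max = 0.05, maf_min = 0.01,
                      hwe_alpha = 1e-6, het_sd = 5) {
  x <- genotypes$dosages
  if (nrow(x) < 2 || ncol(x) < 1) {
    abort("qc_filter needs at least 2 subjects and 1 SNP.",
          class = "heritkit_config_error")
  }
  report <- list()
  keep_s <- rep(TRUE, nrow(x))
  keep_m <- rep(TRUE, ncol(x))
  iids <- genotypes$subjects$iid
  snps <- genotypes$snp_map$id

  ## 1. sample missingness
  miss_rate <- rowMeans(is.na(x))
  drop <- which(miss_rate > miss_max)
  if (length(drop)) {
    report$miss <- tibble(unit = "sample", id = iids[drop],
                          reason = "missingness", value = miss_rate[drop])
    keep_s[drop] <- FALSE
  }

  ## 2. SNP minor allele frequency (mean dosage / 2; fractional dosages count)
  xs <- x[keep_s, , drop = FALSE]
  p <- colMeans(xs, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop <- which(maf < maf_min | is.na(maf))
  if (length(drop)) {
    report$maf <- tibble(unit = "snp", id = snps[drop],
                         reason = "maf", value = maf[drop])
    keep_m[drop] <- FALSE
  }

  ## 3. HWE chi-square on hard calls
  xs <- x[keep_s, keep_m, drop = FALSE]
  hw <- hwe_pvalues(xs)
  drop_local <- which(hw < hwe_alpha)
  if (length(drop_local)) {
    ids_local <- snps[keep_m][drop_local]
    report$hwe <- tibble(unit = "snp", id = ids_local,
                         reason = "hwe", value = hw[drop_local])
    keep_m[match(ids_local, snps)] <- FALSE
  }

  ## 4. sample heterozygosity outliers on hard calls
  xs <- x[keep_s, keep_m, drop = FALSE]
  hard <- !is.na(xs) & xs == round(xs)
  het <- rowSums(xs == 1 & hard, na.rm = TRUE) / pmax(1, rowSums(hard))
  mu <- mean(het); s <- sd(het)
  if (is.finite(s) && s > 0) {
    drop_local <- which(abs(het - mu) > het_sd * s)
    if (length(drop_local)) {
      ids_local <- iids[keep_s][drop_local]
      report$het <- tibble(unit = "sample", id = ids_local,
                           reason = "heterozygosity", value = het[drop_local])
      keep_s[match(ids_local, iids)] <- FALSE
    }
  }

  if (!any(keep_s) || !any(keep_m)) {
    abort("empty after QC: every sample or SNP was removed.",
          class = "heritkit_qc_empty_error")
  }
  out <- subset_genotypes(genotypes, which(keep_s), which(keep_m))
  structure(list(
    genotypes = out,
    report = if (length(report)) bind_rows(report) else
      tibble(unit = character(), id = character(), reason = character(),
             value = double()),
    thresholds = c(miss_max = miss_max, maf_min = maf_min,
                   hwe_alpha = hwe_alpha, het_sd = het_sd),
    counts = tibble(
      unit = c("sample", "snp"),
      before = c(nrow(x), ncol(x)),
      after = c(sum(keep_s), sum(keep_m))
    )
  ), class = "qc_result")
}

# 1-df chi-square HWE p-value per SNP from hard-call genotype counts.
hwe_pvalues <- function(x) {
  hard <- !is.na(x) & x == round(x)
  xh <- x; xh[!hard] <- NA
  n0 <- colSums(xh == 0, na.rm = TRUE)
  n1 <- colSums(xh == 1, na.rm = TRUE)
  n2 <- colSums(xh == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * pmax(1, n))
  e0 <- n * (1 - p)^2; e1 <- n * 2 * p * (1 - p); e2 <- n * p^2
  chi <- rep(0, length(n))
  ok <- n > 0 & p > 0 & p < 1
  chi[ok] <- (n0[ok] - e0[ok])^2 / e0[ok] +
    (n1[ok] - e1[ok])^2 / e1[ok] +
    (n2[ok] - e2[ok])^2 / e2[ok]
  out <- pchisq(chi, df = 1, lower.tail = FALSE)
  out[!ok] <- 1  # monomorphic SNPs are caught by the MAF rule, not HWE
  out
}

#' Iterate [qc_filter()] to a fixpoint
#'
#' Re-applies the filter until a pass removes nothing (the heterozygosity
#' rule depends on the retained set). On well-behaved data the fixpoint is
#' reached within a handful of passes.
#'
#' @inheritParams qc_filter
#' @param max_pass Maximum number of passes before giving up with an error.
#' @return A `qc_result` whose `report` accumulates all passes and which
#'   carries the number of passes in `$passes`.
#' @export
qc_fixpoint <- function(genotypes, miss_max = 0.05, maf_min = 0.01,
                        hwe_alpha = 1e-6, het_sd = 5, max_pass = 5) {
  reports <- list()
  current <- genotypes
  for (pass in seq_len(max_pass)) {
    res <- qc_filter(current, miss_max, maf_min, hwe_alpha, het_sd)
    reports[[pass]] <- res$report
    removed <- nrow(res$report)
    current <- res$genotypes
    if (removed == 0) {
      res$report <- bind_rows(reports)
      res$passes <- pass
      return(res)
    }
  }
  abort(sprintf("QC did not reach a fixpoint in %d passes.", max_pass),
        class = "heritkit_qc_error")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  print(x$counts)
  if (nrow(x$report)) {
    tab <- table(x$report$reason)
    cat("  removals:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  } else cat("  removals: none\n")
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param qc A `qc_result`.
#' @param path Output TSV path.
#' @export
write_qc_report <- function(qc, path) {
  write.table(qc$report, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
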