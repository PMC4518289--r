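# Small deterministic fixtures shared across test files.

# Genotype matrix from a bare dosage matrix, default metadata.
toy_genotypes <- function(dosages, chrom = "1", spacing = 1000L) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages); m <- ncol(dosages)
  genotype_matrix(
    dosages,
    tibble::tibble(fid = sprintf("F%03d", seq_len(n)),
                   iid = sprintf("I%03d", seq_len(n))),
    tibble::tibble(id = sprintf("s%03d", seq_len(m)), chrom = chrom,
                   pos = 1L + (seq_len(m) - 1L) * spacing,
                   a1 = "A", a2 = "B")
  )
}

# Random polymorphic dosage matrix (independent SNPs, common frequencies).
random_dosages <- function(n, m, seed, maf = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  repeat {
    x <- sapply(p, function(pi) rbinom(n, 2L, pi))
    f <- colMeans(x) / 2
    if (all(f > 0 & f < 1)) return(x)
  }
}

# Brute-force GCTA GRM estimator: explicit double loop over subject pairs.
brute_force_grm <- function(x) {
  n <- nrow(x); m <- ncol(x)
  p <- colMeans(x, na.rm = TRUE) / 2
  a <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j == k) {
        acc <- 0; cnt <- 0
        for (i in seq_len(m)) {
          if (is.na(x[j, i])) next
          acc <- acc + (x[j, i]^2 - (1 + 2 * p[i]) * x[j, i] + 2 * p[i]^2) /
            (2 * p[i] * (1 - p[i]))
          cnt <- cnt + 1
        }
        a[j, j] <- 1 + acc / cnt
      } else {
        acc <- 0; cnt <- 0
        for (i in seq_len(m)) {
          if (is.na(x[j, i]) || is.na(x[k, i])) next
          acc <- acc + (x[j, i] - 2 * p[i]) * (x[k, i] - 2 * p[i]) /
            (2 * p[i] * (1 - p[i]))
          cnt <- cnt + 1
        }
        a[j, k] <- acc / cnt
      }
    }
  }
  a
}

# Exhaustive maximum subject set with no pair above threshold (n <= 12).
exhaustive_prune_optimum <- function(a, threshold) {
  n <- nrow(a)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    keep <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(keep) <= best) next
    sub <- a[keep, keep, drop = FALSE]
    diag(sub) <- -Inf
    if (all(sub <= threshold)) best <- length(keep)
  }
  best
}

# REML log-likelihood via the multivariate-normal density of an orthonormal
# error-contrast basis — independent of the package's evaluation route.
contrast_reml_loglik <- function(y, X, v) {
  n <- length(y); p <- ncol(X)
  qx <- qr(X)
  k <- qr.Q(qx, complete = TRUE)[, (p + 1):n, drop = FALSE]
  kv <- t(k) %*% v %*% k
  ky <- drop(t(k) %*% y)
  ch <- chol(kv)
  quad <- sum(ky * backsolve(ch, forwardsolve(t(ch), ky)))
  -0.5 * (2 * sum(log(diag(ch))) + quad + (n - p) * log(2 * pi))
}

# Hand-built LD matrix object for weighting tests.
manual_ld_matrix <- function(r2, snp_ids, window_bp = 1e6) {
  structure(list(r2 = Matrix::Matrix(r2, sparse = TRUE),
                 snp_ids = snp_ids, window_bp = window_bp),
            class = "ld_matrix")
}
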