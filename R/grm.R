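new_grm_result <- function(values, pair_snp_counts, subjects, n_snps_total) {
  structure(list(values = values, pair_snp_counts = pair_snp_counts,
                 subjects = as_tibble(subjects),
                 n_snps_total = n_snps_total),
            class = "grm_result")
}

#' @export
print.grm_result <- function(x, ...) {
  n <- nrow(x$values)
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<grm_result> %d subjects, %d SNPs\n", n, x$n_snps_total))
  cat(sprintf("  mean diagonal: %.4f | off-diagonal mean: %.5f sd: %.5f\n",
              mean(diag(x$values)), mean(off), sd(off)))
  invisible(x)
}

#' Compute the genetic relationship matrix
#'
#' GCTA-style estimator with in-sample allele frequencies `p_i`. Off-diagonal
#' entries average `(x_ij - 2p_i)(x_ik - 2p_i) / (2p_i(1 - p_i))` over the
#' SNPs non-missing in both subjects; diagonal entries use the
#' inbreeding-adjusted form
#' `1 + mean[(x^2 - (1 + 2p)x + 2p^2) / (2p(1 - p))]` over the subject's
#' non-missing SNPs.
#'
#' @param genotypes A [genotype_matrix()]; every SNP must be polymorphic
#'   (run [qc_filter()] first).
#' @param diagonal `"gcta"` (default) for the inbreeding-adjusted diagonal
#'   above — the estimator the GRM-binary ecosystem exchanges — or
#'   `"simple"` for the squared-standardized form
#'   `mean[(x - 2p)^2 / (2p(1 - p))]`. The two agree in expectation under
#'   Hardy-Weinberg but differ per subject; only the simple form makes the
#'   diagonal exactly equal an off-diagonal entry against an identical
#'   genotype row.
#' @return A `grm_result`: `values` (symmetric n x n), `pair_snp_counts`,
#'   `subjects`, `n_snps_total`.
#' @examples
#' g <- simulate_genotypes(sim_config(n_subjects = 30, n_snps = 200, seed = 1))
#' grm <- compute_grm(g)
#' mean(diag(grm$values))
#' @export
compute_grm <- function(genotypes, diagonal = c("gcta", "simple")) {
  diagonal <- match.arg(diagonal)
  x <- genotypes$dosages
  std <- standardize_dosages(x)
  w <- std$w
  p <- std$freq
  nonmiss <- !is.na(x)
  if (all(nonmiss)) {
    counts <- matrix(ncol(x), nrow(x), nrow(x))
  } else {
    counts <- tcrossprod(nonmiss * 1)
  }
  if (any(counts < 1)) {
    abort("some subject pair shares no non-missing SNP.",
          class = "heritkit_format_error")
  }
  a <- tcrossprod(w) / counts

  if (diagonal == "gcta") {
    # inbreeding-adjusted diagonal
    denom <- 2 * p * (1 - p)
    num <- x^2 - sweep(x, 2, 1 + 2 * p, "*")
    num <- sweep(num, 2, 2 * p^2, "+")
    num <- sweep(num, 2, denom, "/")
    diag(a) <- 1 + rowSums(num, na.rm = TRUE) / diag(counts)
  }  # "simple": tcrossprod already put mean[(x - 2p)^2 / 2pq] on the diagonal

  new_grm_result(a, counts, genotypes$subjects, n_snps_total = ncol(x))
}

#' Prune cryptic relatedness from a GRM
#'
#' Greedy removal: while any off-diagonal entry exceeds `threshold`, drop the
#' subject participating in the most above-threshold pairs (ties broken by
#' removing the later subject in input order), so exactly one member of each
#' isolated related pair is excluded. The returned set has no pair above
#' threshold.
#'
#' @param grm A `grm_result` (or bare symmetric matrix with ids as dimnames).
#' @param threshold Relatedness cutoff (the conventional choices are 0.025
#'   and 0.1); entries strictly greater are pruned.
#' @return Character vector of kept subject ids (IIDs), in input order, with
#'   removed ids in `attr(, "removed")`.
#' @export
prune_related <- function(grm, threshold) {
  if (threshold <= 0) {
    abort("threshold must be positive.", class = "heritkit_config_error")
  }
  a <- if (inherits(grm, "grm_result")) grm$values else as.matrix(grm)
  ids <- if (inherits(grm, "grm_result")) grm$subjects$iid else
    (rownames(a) %||% as.character(seq_len(nrow(a))))
  adj <- a > threshold
  diag(adj) <- FALSE
  alive <- rep(TRUE, nrow(a))
  removed <- character()
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (all(deg == 0)) break
    worst <- which(deg == max(deg))
    victim <- worst[length(worst)]  # later subject on ties
    alive[victim] <- FALSE
    adj[victim, ] <- FALSE
    adj[, victim] <- FALSE
    removed <- c(removed, ids[victim])
  }
  out <- ids[alive]
  attr(out, "removed") <- removed
  out
}

#' Principal components of a GRM
#'
#' Eigenvectors of the relationship matrix for the `k` largest eigenvalues,
#' unit norm, eigenvalue-descending order; each column is sign-fixed so its
#' largest-magnitude loading is positive. These are the ancestry covariates
#' appended to the fixed effects.
#'
#' @param grm A `grm_result` or symmetric matrix.
#' @param k Number of components (`k < n`).
#' @return n x k matrix with columns `PC1..PCk` and eigenvalues in
#'   `attr(, "eigenvalues")`.
#' @export
grm_pca <- function(grm, k = 10) {
  a <- if (inherits(grm, "grm_result")) grm$values else as.matrix(grm)
  n <- nrow(a)
  if (k >= n) {
    abort(sprintf("k = %d must be smaller than n = %d.", k, n),
          class = "heritkit_config_error")
  }
  es <- eigen(a, symmetric = TRUE)
  vec <- es$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  colnames(vec) <- paste0("PC", seq_len(k))
  if (inherits(grm, "grm_result")) rownames(vec) <- grm$subjects$iid
  attr(vec, "eigenvalues") <- es$values[seq_len(k)]
  vec
}

#' Write GRM eigenvectors as a PLINK-style covariate file
#'
#' @param pcs Matrix from [grm_pca()] (rownames are IIDs).
#' @param subjects Subject tibble with `fid`, `iid` matching the rows.
#' @param path Output path (whitespace-delimited `FID IID PC1..PCk`).
#' @export
write_pca_covariates <- function(pcs, subjects, path) {
  df <- data.frame(fid = subjects$fid, iid = subjects$iid, pcs)
  write.table(df, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
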