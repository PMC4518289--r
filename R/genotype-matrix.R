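#' Genotype matrix container
#'
#' Holds an n-subjects-by-M-SNPs allele-dosage matrix together with the
#' subject table and SNP map. Dosages count copies of allele `a1` and are 0,
#' 1, 2, `NA` (missing), or fractional in `[0, 2]` for imputed input.
#'
#' @param dosages Numeric n x M matrix; values in `[0, 2]` or `NA`.
#' @param subjects Tibble with columns `fid`, `iid` (n rows).
#' @param snp_map Tibble with columns `id`, `chrom`, `pos` (1-based bp),
#'   `a1`, `a2` (M rows); positions nondecreasing within chromosome.
#'   Extra columns (e.g. a generating `freq` or LD `block`) are carried along.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, subjects, snp_map) {
  dosages <- as.matrix(dosages)
  subjects <- as_tibble(subjects)
  snp_map <- as_tibble(snp_map)
  if (!all(c("fid", "iid") %in% names(subjects))) {
    abort("subjects must have columns fid, iid.", class = "heritkit_format_error")
  }
  if (!all(c("id", "chrom", "pos", "a1", "a2") %in% names(snp_map))) {
    abort("snp_map must have columns id, chrom, pos, a1, a2.",
          class = "heritkit_format_error")
  }
  if (nrow(dosages) != nrow(subjects) || ncol(dosages) != nrow(snp_map)) {
    abort(sprintf(
      "dosage dimensions %d x %d do not match %d subjects x %d SNPs.",
      nrow(dosages), ncol(dosages), nrow(subjects), nrow(snp_map)),
      class = "heritkit_format_error")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    abort("dosages must lie in [0, 2] or be NA.", class = "heritkit_format_error")
  }
  unsorted <- tapply(snp_map$pos, snp_map$chrom, function(p) is.unsorted(p))
  if (any(unlist(unsorted))) {
    abort("snp_map positions must be nondecreasing within each chromosome.",
          class = "heritkit_format_error")
  }
  dimnames(dosages) <- list(subjects$iid, snp_map$id)
  structure(list(dosages = dosages, subjects = subjects, snp_map = snp_map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d subjects x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  nmiss <- sum(is.na(x$dosages))
  cat(sprintf("  chromosomes: %s | missing calls: %d (%.2f%%)\n",
              paste(unique(x$snp_map$chrom), collapse = ", "),
              nmiss, 100 * nmiss / length(x$dosages)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# Subset by subject / SNP index vectors, keeping metadata aligned.
subset_genotypes <- function(geno, subjects = NULL, snps = NULL) {
  i <- if (is.null(subjects)) seq_len(nrow(geno$dosages)) else subjects
  j <- if (is.null(snps)) seq_len(ncol(geno$dosages)) else snps
  genotype_matrix(geno$dosages[i, j, drop = FALSE],
                  geno$subjects[i, , drop = FALSE],
                  geno$snp_map[j, , drop = FALSE])
}

# Column-standardize dosages by in-sample frequency: (x - 2p) / sqrt(2p(1-p)).
# Missing entries become 0 (their contribution is dropped by pair counts).
standardize_dosages <- function(dosages, freq = NULL) {
  if (is.null(freq)) freq <- colMeans(dosages, na.rm = TRUE) / 2
  mono <- which(freq <= 0 | freq >= 1)
  if (length(mono) > 0) {
    abort(sprintf("monomorphic SNP(s) reached standardization: %s",
                  paste(head(colnames(dosages)[mono], 5), collapse = ", ")),
          class = "heritkit_monomorphic_error")
  }
  w <- sweep(dosages, 2, 2 * freq, "-")
  w <- sweep(w, 2, sqrt(2 * freq * (1 - freq)), "/")
  w[is.na(w)] <- 0
  list(w = w, freq = freq)
}
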