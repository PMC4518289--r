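#' Label SNPs genic or intergenic from a gene table
#'
#' A SNP is genic iff its 1-based position lies within
#' `[gene_start - flank_bp, gene_end + flank_bp]` (closed interval, 1-based,
#' after converting the BED 0-based half-open input) for any gene — the
#' gene-span-plus-20-kb-flanks definition under which genic and intergenic
#' coverage of the genome are roughly equal.
#'
#' @param snp_map Tibble with `id`, `chrom`, `pos`.
#' @param gene_table Gene tibble in BED convention (`chrom`, `start` 0-based,
#'   `end` exclusive), e.g. from [read_gene_bed()] or [simulate_annotation()].
#' @param flank_bp Flank added on each side of every gene span.
#' @return Annotation track tibble: `snp_id`, `chrom`, `pos`, `score` (the
#'   0/1 genic indicator), `category` (`"genic"`/`"intergenic"`).
#' @examples
#' map <- tibble::tibble(id = c("a", "b"), chrom = "1", pos = c(79999, 80000))
#' genes <- tibble::tibble(chrom = "1", start = 99999L, end = 200000L,
#'                         name = "g1")
#' annotate_genic(map, genes)$category
#' @export
annotate_genic <- function(snp_map, gene_table, flank_bp = 20000) {
  if (nrow(gene_table) > 0) {
    if (any(gene_table$start >= gene_table$end)) {
      abort("gene_table has intervals with start >= end.",
            class = "heritkit_format_error")
    }
    shared <- intersect(unique(snp_map$chrom), unique(gene_table$chrom))
    if (length(shared) == 0) {
      abort(sprintf(
        "no shared chromosomes: SNP map has {%s}, gene table has {%s}.",
        paste(unique(snp_map$chrom), collapse = ","),
        paste(unique(gene_table$chrom), collapse = ",")),
        class = "heritkit_format_error")
    }
  }
  genic <- rep(FALSE, nrow(snp_map))
  for (ch in unique(snp_map$chrom)) {
    si <- which(snp_map$chrom == ch)
    genes_ch <- gene_table[gene_table$chrom == ch, , drop = FALSE]
    genic[si] <- flag_genic(snp_map$pos[si], genes_ch, flank_bp)
  }
  tibble(snp_id = snp_map$id, chrom = snp_map$chrom, pos = snp_map$pos,
         score = as.numeric(genic),
         category = ifelse(genic, "genic", "intergenic"))
}

#' Windowed pairwise LD (r-squared) matrix
#'
#' Squared Pearson correlation of dosage columns for every same-chromosome
#' SNP pair within `window_bp`; missing dosages are pairwise-deleted. Stored
#' sparse (entries outside the window are structural zeros).
#'
#' @param genotypes A [genotype_matrix()] (post-QC: no zero-variance SNPs).
#' @param window_bp Base-pair window; pairs farther apart are not computed.
#' @return List of class `ld_matrix`: `r2` (sparse symmetric, unit diagonal),
#'   `snp_ids`, `window_bp`.
#' @export
compute_ld_matrix <- function(genotypes, window_bp = 1e6) {
  x <- genotypes$dosages
  v <- apply(x, 2, var, na.rm = TRUE)
  if (any(!is.finite(v) | v == 0)) {
    bad <- genotypes$snp_map$id[which(!is.finite(v) | v == 0)]
    abort(sprintf("zero-variance SNP(s): %s (run qc_filter first).",
                  paste(head(bad, 5), collapse = ", ")),
          class = "heritkit_monomorphic_error")
  }
  m <- ncol(x)
  has_na <- anyNA(x)
  ii <- integer(); jj <- integer(); vv <- double()
  for (ch in unique(genotypes$snp_map$chrom)) {
    cols <- which(genotypes$snp_map$chrom == ch)
    pos <- genotypes$snp_map$pos[cols]
    if (!has_na) {
      z <- scale(x[, cols, drop = FALSE])
      nr <- nrow(z)
      for (lag in seq_len(length(cols) - 1)) {
        pairs <- seq_len(length(cols) - lag)
        within <- pairs[pos[pairs + lag] - pos[pairs] <= window_bp]
        if (length(within) == 0) break
        r <- colSums(z[, within, drop = FALSE] *
                       z[, within + lag, drop = FALSE]) / (nr - 1)
        ii <- c(ii, cols[within]); jj <- c(jj, cols[within + lag])
        vv <- c(vv, r^2)
      }
    } else {
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (b <= a) next
          if (pos[b] - pos[a] > window_bp) break
          r <- suppressWarnings(
            cor(x[, cols[a]], x[, cols[b]], use = "pairwise.complete.obs"))
          ii <- c(ii, cols[a]); jj <- c(jj, cols[b]); vv <- c(vv, r^2)
        }
      }
    }
  }
  r2 <- Matrix::sparseMatrix(i = c(ii, seq_len(m)), j = c(jj, seq_len(m)),
                             x = c(vv, rep(1, m)), dims = c(m, m),
                             symmetric = TRUE)
  structure(list(r2 = r2, snp_ids = genotypes$snp_map$id,
                 window_bp = window_bp),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  m <- length(x$snp_ids)
  nnz <- (Matrix::nnzero(x$r2) - m) / 2
  cat(sprintf("<ld_matrix> %d SNPs, window %g bp, %d stored pairs\n",
              m, x$window_bp, nnz))
  invisible(x)
}

#' LD-weight an annotation score track
#'
#' Smooths raw per-SNP scores with the LD matrix so tagging SNPs inherit
#' their partners' annotation: the weighted score is the self-inclusive
#' r2-weighted average `s_i = sum_j r2_ij s_j / sum_j r2_ij` over scored SNPs
#' within the window (with `r2_ii = 1`), a convex combination that keeps
#' scores on the raw scale. SNPs with a missing raw score and no scored LD
#' partner get a missing weighted score and are dropped from later analysis.
#' `normalize = FALSE` gives the raw matrix-vector product instead.
#'
#' @param ld An `ld_matrix` from [compute_ld_matrix()].
#' @param track Annotation track tibble with `snp_id` and `score` (missing
#'   scores `NA`); row order must match `ld$snp_ids`.
#' @param normalize Divide by the summed r2 of scored partners (default).
#' @return The track with a `weighted` column added.
#' @export
ld_weight_scores <- function(ld, track, normalize = TRUE) {
  if (!identical(as.character(track$snp_id), as.character(ld$snp_ids))) {
    abort("track snp_ids must match the LD matrix (same order).",
          class = "heritkit_format_error")
  }
  scored <- !is.na(track$score)
  if (!any(scored)) {
    abort("no scored SNPs overlap the LD matrix.",
          class = "heritkit_format_error")
  }
  s0 <- ifelse(scored, track$score, 0)
  num <- as.vector(ld$r2 %*% s0)
  den <- as.vector(ld$r2 %*% as.numeric(scored))
  out <- track
  out$weighted <- ifelse(den > 0, num / den, NA_real_)
  if (!normalize) out$weighted <- ifelse(den > 0, num, NA_real_)
  out
}

#' Split SNPs at the median of a score track
#'
#' Scored SNPs with score strictly above the median are labelled `high`,
#' those at or below `low` — the threshold that partitions the genome evenly
#' into low- and high-scoring halves. Missing-score SNPs keep `NA` category
#' and are excluded downstream.
#'
#' @param track Annotation track tibble; the split uses `weighted` when
#'   present, else `score` (override with `column`).
#' @param column Name of the score column to split on.
#' @return The track with `category` set to `"low"`/`"high"` (`NA` for
#'   unscored SNPs) and the threshold in `attr(, "median")`.
#' @export
median_split <- function(track,
                         column = if ("weighted" %in% names(track))
                           "weighted" else "score") {
  s <- track[[column]]
  scored <- !is.na(s)
  if (sum(scored) < 2) {
    abort("median_split needs at least 2 scored SNPs.",
          class = "heritkit_config_error")
  }
  if (diff(range(s[scored])) == 0) {
    abort("degenerate split: all scores identical.",
          class = "heritkit_degenerate_error")
  }
  med <- median(s[scored])
  out <- track
  out$category <- ifelse(scored, ifelse(s > med, "high", "low"), NA_character_)
  attr(out, "median") <- med
  out
}

#' Correlation between two annotation score tracks
#'
#' Pearson correlation over the SNPs scored in both tracks, and its square
#' (the shared variance between the annotations).
#'
#' @param track_a,track_b Annotation tracks (tibbles with `snp_id` and a
#'   score column) or bare numeric vectors of equal length.
#' @param column Score column used for tibble inputs (`weighted` if present).
#' @return Named list: `r`, `r_squared`, `n` (SNPs in both).
#' @examples
#' score_correlation(c(0, 1, 2), c(2, 1, 0))$r
#' @export
score_correlation <- function(track_a, track_b,
                              column = NULL) {
  get_scores <- function(tr) {
    if (is.numeric(tr)) return(tibble(snp_id = seq_along(tr), s = tr))
    col <- column %||% if ("weighted" %in% names(tr)) "weighted" else "score"
    tibble(snp_id = tr$snp_id, s = tr[[col]])
  }
  a <- get_scores(track_a); b <- get_scores(track_b)
  merged <- merge(a, b, by = "snp_id")
  merged <- merged[complete.cases(merged), ]
  if (nrow(merged) < 3) {
    abort("score_correlation needs at least 3 SNPs scored in both tracks.",
          class = "heritkit_config_error")
  }
  if (sd(merged$s.x) == 0 || sd(merged$s.y) == 0) {
    abort("zero variance in a score track.",
          class = "heritkit_degenerate_error")
  }
  r <- cor(merged$s.x, merged$s.y)
  list(r = r, r_squared = r^2, n = nrow(merged))
}

#' Build a disjoint SNP partition from category labels
#'
#' @param track Annotation track tibble with `snp_id` and `category`
#'   (`NA`-category SNPs are dropped), or a named list of such tracks whose
#'   label sets are combined by interaction.
#' @return Named list of SNP id character vectors, one per category; errors
#'   if any SNP carries two labels or a category is empty.
#' @export
build_partition <- function(track) {
  if (anyDuplicated(track$snp_id[!is.na(track$category)])) {
    dup <- track$snp_id[duplicated(track$snp_id) & !is.na(track$category)]
    abort(sprintf("overlapping categories for SNP(s): %s",
                  paste(head(unique(dup), 5), collapse = ", ")),
          class = "heritkit_format_error")
  }
  keep <- !is.na(track$category)
  if (!any(keep)) {
    abort("no categorized SNPs to partition.", class = "heritkit_format_error")
  }
  sets <- split(as.character(track$snp_id[keep]),
                as.character(track$category[keep]))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty)) {
    abort(sprintf("empty categories: %s", paste(empty, collapse = ", ")),
          class = "heritkit_format_error")
  }
  sets
}

#' Write a SNP partition as TSV
#'
#' @param partition Named list from [build_partition()].
#' @param path Output path (`snp_id`, `category`).
#' @export
write_partition_tsv <- function(partition, path) {
  df <- data.frame(
    snp_id = unlist(partition, use.names = FALSE),
    category = rep(names(partition), lengths(partition))
  )
  write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
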