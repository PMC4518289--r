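#' Simulate LD-blocked common-SNP genotypes
#'
#' Builds two haplotypes per subject. Within an LD block, haplotype alleles
#' follow a stationary first-order Markov chain with lag-1 allele correlation
#' `ld_rho` (a copy chain: each allele is a copy of its left neighbour with
#' probability `ld_rho`, otherwise a fresh Bernoulli draw); haplotypes are
#' independent across blocks. SNP positions are 1-based with fixed spacing on
#' one synthetic chromosome.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()] whose `snp_map` carries the generating
#'   frequency (`freq`) and LD block index (`block`).
#' @examples
#' g <- simulate_genotypes(sim_config(n_subjects = 20, n_snps = 50, seed = 1))
#' dim(g)
#' @export
simulate_genotypes <- function(config) {
  config <- validate_sim_config(config)
  with_sim_seed(config$seed, 101L, {
    n <- config$n_subjects
    m <- config$n_snps
    block <- make_blocks(m, config$block_size)
    freq <- draw_frequencies(block, config)
    h <- simulate_haplotypes(2L * n, freq, block, config$ld_rho)
    x <- h[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
      h[seq(2L, 2L * n, by = 2L), , drop = FALSE]
    subjects <- tibble(
      fid = sprintf("F%04d", seq_len(n)),
      iid = sprintf("I%04d", seq_len(n))
    )
    snp_map <- tibble(
      id = sprintf("snp%06d", seq_len(m)),
      chrom = config$chrom,
      pos = 1L + (seq_len(m) - 1L) * config$spacing_bp,
      a1 = "A", a2 = "B",
      freq = freq, block = block
    )
    genotype_matrix(x, subjects, snp_map)
  })
}

make_blocks <- function(m, block_size) {
  as.integer(ceiling(seq_len(m) / block_size))
}

# One frequency per block when the chain is correlated (the target lag-1
# correlation is unattainable between frequency-mismatched Bernoulli alleles);
# free per-SNP draws when ld_rho = 0.
draw_frequencies <- function(block, config) {
  mr <- config$maf_range
  if (config$ld_rho > 0) {
    per_block <- runif(max(block), mr[1], mr[2])
    per_block[block]
  } else {
    runif(length(block), mr[1], mr[2])
  }
}

simulate_haplotypes <- function(n_hap, freq, block, rho) {
  m <- length(freq)
  h <- matrix(0L, n_hap, m)
  for (b in unique(block)) {
    cols <- which(block == b)
    h[, cols[1]] <- rbinom(n_hap, 1L, freq[cols[1]])
    for (j in cols[-1]) {
      keep <- runif(n_hap) < rho
      fresh <- rbinom(n_hap, 1L, freq[j])
      h[, j] <- ifelse(keep, h[, j - 1L], fresh)
    }
  }
  h
}

#' Simulate gene boundaries and conservation scores over a SNP map
#'
#' Places non-overlapping synthetic genes so that the *flanked* genic span
#' (gene body plus `flank_bp` on each side, the definition used by
#' [annotate_genic()]) covers about `frac_genic` of the SNP span, and assigns
#' each SNP a conservation score in `[0, 1]` from a Beta distribution whose
#' mean is elevated inside gene bodies and wanders block-to-block (spatial
#' autocorrelation). A configurable fraction of SNPs gets a missing score,
#' emulating unscored genome positions that downstream analysis drops.
#'
#' @param snp_map SNP map tibble (`id`, `chrom`, `pos`, optionally `block`).
#' @param config A [sim_config()].
#' @return List with `scores` (an annotation track tibble: `snp_id`, `chrom`,
#'   `pos`, `score`) and `genes` (a BED-convention gene table: `chrom`,
#'   `start` 0-based, `end` exclusive, `name`).
#' @export
simulate_annotation <- function(snp_map, config) {
  config <- validate_sim_config(config)
  if (is.unsorted(snp_map$pos)) {
    abort("snp_map positions must be sorted.", class = "heritkit_config_error")
  }
  with_sim_seed(config$seed, 202L, {
    span_end <- max(snp_map$pos)
    genes <- place_genes(span_end, config$frac_genic, config$flank_bp,
                         chrom = snp_map$chrom[1])
    genic <- flag_genic(snp_map$pos, genes, config$flank_bp)
    in_body <- flag_genic(snp_map$pos, genes, 0)

    block <- snp_map$block %||% make_blocks(nrow(snp_map), config$block_size)
    block_shift <- rnorm(max(block), 0, 0.5)[block]
    base_logit <- ifelse(in_body, 0.4, -1.1)  # means ~0.60 genic, ~0.25 outside
    mu <- plogis_safe(base_logit + block_shift)
    conc <- 8
    score <- rbeta(nrow(snp_map), mu * conc, (1 - mu) * conc)
    miss <- runif(nrow(snp_map)) < config$missing_score_fraction
    score[miss] <- NA_real_

    list(
      scores = tibble(snp_id = snp_map$id, chrom = snp_map$chrom,
                      pos = snp_map$pos, score = score,
                      genic = genic),
      genes = genes
    )
  })
}

plogis_safe <- function(x) 1 / (1 + exp(-x))

# One gene per equal-width slot with uniform jitter; the flanked spans
# therefore never overlap and jointly cover ~frac_genic of [1, span_end].
place_genes <- function(span_end, frac_genic, flank_bp, chrom,
                        gene_length_bp = 80000) {
  if (frac_genic <= 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  if (frac_genic >= 1) {
    return(tibble(chrom = chrom, start = 0L, end = as.integer(span_end),
                  name = "gene0001"))
  }
  eff_len <- gene_length_bp + 2 * flank_bp
  n_genes <- max(1L, floor(frac_genic * span_end / eff_len))
  slot <- span_end / n_genes
  body_len <- min(gene_length_bp, max(1, floor(slot) - 2 * flank_bp))
  offsets <- runif(n_genes, 0, max(0, slot - body_len - 2 * flank_bp))
  start1 <- floor((seq_len(n_genes) - 1) * slot + flank_bp + offsets) + 1
  end1 <- pmin(start1 + body_len - 1, span_end)
  tibble(chrom = chrom, start = as.integer(start1 - 1L),
         end = as.integer(end1), name = sprintf("gene%04d", seq_len(n_genes)))
}

# 1-based positions against a BED-convention gene table, closed flanks.
flag_genic <- function(pos, genes, flank_bp) {
  if (nrow(genes) == 0) return(rep(FALSE, length(pos)))
  q <- IRanges::IRanges(start = pos, width = 1L)
  s <- IRanges::IRanges(start = pmax(1L, genes$start + 1L - flank_bp),
                        end = genes$end + flank_bp)
  IRanges::overlapsAny(q, s)
}

#' Simulate a polygenic phenotype with category-specific enrichment
#'
#' Draws per-SNP effects within each annotation category, builds the genetic
#' value from standardized dosages, rescales it so the realized genetic
#' variance equals `h2_total` exactly (category ratios preserved; disable with
#' `rescale_exact = FALSE` in the config), and adds covariate effects (a
#' nonlinear age trend, sex, cohort) plus Gaussian noise of variance
#' `1 - h2_total`.
#'
#' @param genotypes A [genotype_matrix()].
#' @param annotation Optional tibble mapping `snp_id` to `category`; `NULL`
#'   puts every SNP in one genome-wide category.
#' @param config A [sim_config()]. When `h2_by_category` is empty the single
#'   category gets `h2_total`; otherwise categories must appear in
#'   `annotation` and their h2 values must sum to `h2_total` or less (the
#'   final joint rescale targets `h2_total`).
#' @return List of class `phenotype_sim`: `phenotypes` (tibble with `fid`,
#'   `iid`, `y`, covariates, true genetic value `g_true`), `causal` (tibble of
#'   causal SNP ids, categories, effects), `g_by_category` (matrix of
#'   per-category genetic values), `h2_realized`.
#' @export
simulate_phenotype <- function(genotypes, annotation = NULL, config) {
  config <- validate_sim_config(config)
  with_sim_seed(config$seed, 303L, {
    n <- nrow(genotypes$dosages)
    snp_ids <- genotypes$snp_map$id

    if (is.null(annotation)) {
      category <- setNames(rep("all", length(snp_ids)), snp_ids)
    } else {
      category <- setNames(as.character(annotation$category),
                           annotation$snp_id)[snp_ids]
    }
    h2c <- config$h2_by_category
    if (is.null(h2c)) {
      # genome-wide architecture: one category spanning every SNP
      h2c <- c(all = config$h2_total)
      category <- setNames(rep("all", length(snp_ids)), snp_ids)
    }
    missing_cat <- setdiff(names(h2c), unique(category))
    if (length(missing_cat) > 0) {
      abort(sprintf("categories absent from annotation: %s",
                    paste(missing_cat, collapse = ", ")),
            class = "heritkit_config_error")
    }
    cf <- config$causal_fraction_by_category
    if (is.null(cf)) cf <- setNames(rep(0.1, length(h2c)), names(h2c))

    g_by_cat <- matrix(0, n, length(h2c),
                       dimnames = list(NULL, names(h2c)))
    causal <- list()
    for (cat in names(h2c)) {
      in_cat <- which(category == cat & !is.na(category))
      m_causal <- round(length(in_cat) * (cf[[cat]] %||% 0.1))
      if (m_causal == 0) {
        if (h2c[[cat]] > 0) {
          abort(sprintf(
            "category '%s' has h2 = %.3f but zero causal SNPs.", cat, h2c[[cat]]),
            class = "heritkit_config_error")
        }
        next
      }
      idx <- sort(sample(in_cat, m_causal))
      beta <- rnorm(m_causal, 0, sqrt(h2c[[cat]] / m_causal))
      z <- scale(genotypes$dosages[, idx, drop = FALSE])
      g <- drop(z %*% beta)
      if (config$rescale_exact && h2c[[cat]] > 0 && var(g) > 0) {
        g <- g * sqrt(h2c[[cat]] / (var(g) * (n - 1) / n))
      }
      g_by_cat[, cat] <- g
      causal[[cat]] <- tibble(snp_id = snp_ids[idx], category = cat,
                              beta = beta)
    }
    g_total <- rowSums(g_by_cat)
    vg <- var(g_total) * (n - 1) / n
    if (config$rescale_exact && config$h2_total > 0 && vg > 0) {
      s <- sqrt(config$h2_total / vg)
      g_total <- g_total * s
      g_by_cat <- g_by_cat * s
    }

    age <- runif(n, 5, 85)
    sex <- rbinom(n, 1L, 0.52)
    cohort <- sample(sprintf("cohort%d", 1:5), n, replace = TRUE)
    if (config$covariate_effects) {
      az <- (age - mean(age)) / sd(age)
      cohort_eff <- setNames(rnorm(5, 0, 0.2), sprintf("cohort%d", 1:5))
      xg <- 0.25 * az - 0.15 * (az^2 - 1) + 0.2 * sex + cohort_eff[cohort]
    } else {
      xg <- rep(0, n)
    }
    e <- rnorm(n, 0, sqrt(max(0, 1 - config$h2_total)))
    y <- g_total + xg + e

    structure(list(
      phenotypes = tibble(
        fid = genotypes$subjects$fid, iid = genotypes$subjects$iid,
        y = y, age = age, sex = sex, cohort = cohort, g_true = g_total
      ),
      causal = if (length(causal)) bind_rows(causal) else
        tibble(snp_id = character(), category = character(), beta = double()),
      g_by_category = g_by_cat,
      h2_realized = var(g_total) * (n - 1) / n
    ), class = "phenotype_sim")
  })
}

#' Simulate MZ/DZ twin-pair phenotypes under the ACE model
#'
#' Pair phenotypes are bivariate normal with unit marginal variance and
#' correlation `a2 + c2` (MZ) or `a2/2 + c2` (DZ), where
#' `config$ace_true = (a2, c2, e2)`.
#'
#' @param config A [sim_config()].
#' @return Tibble of class `twin_dataset` with columns `pair_id`, `zygosity`
#'   (`"MZ"`/`"DZ"`), `y1`, `y2`.
#' @examples
#' tw <- simulate_twins(sim_config(n_mz_pairs = 10, n_dz_pairs = 10, seed = 1))
#' table(tw$zygosity)
#' @export
simulate_twins <- function(config) {
  config <- validate_sim_config(config)
  with_sim_seed(config$seed, 404L, {
    a2 <- config$ace_true[1]; c2 <- config$ace_true[2]
    draw_pairs <- function(n_pairs, r) {
      z1 <- rnorm(n_pairs)
      z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n_pairs)
      cbind(z1, z2)
    }
    mz <- draw_pairs(config$n_mz_pairs, a2 + c2)
    dz <- draw_pairs(config$n_dz_pairs, a2 / 2 + c2)
    out <- tibble(
      pair_id = c(sprintf("MZ%04d", seq_len(config$n_mz_pairs)),
                  sprintf("DZ%04d", seq_len(config$n_dz_pairs))),
      zygosity = rep(c("MZ", "DZ"), c(config$n_mz_pairs, config$n_dz_pairs)),
      y1 = c(mz[, 1], dz[, 1]),
      y2 = c(mz[, 2], dz[, 2])
    )
    class(out) <- c("twin_dataset", class(out))
    out
  })
}

#' Plant cryptic relatedness into a simulated genotype matrix
#'
#' For each planted pair, the second subject's genotype is re-drawn so that a
#' fraction `2 * related_kinship` of LD blocks shares one haplotype with the
#' first subject (sampled consistently from the first subject's genotype),
#' the other haplotype being a fresh draw from the block's Markov chain. The
#' expected GRM entry for a planted pair is `related_kinship`. Pairs are
#' consecutive subjects `(1,2), (3,4), ...`.
#'
#' @param genotypes A [genotype_matrix()] from [simulate_genotypes()] (its
#'   `snp_map` must carry `freq` and `block`).
#' @param config A [sim_config()] with `n_related_pairs > 0` (zero returns
#'   the input unchanged).
#' @return The modified [genotype_matrix()]; planted pairs are recorded in
#'   `attr(, "planted_pairs")` as a tibble of subject index pairs.
#' @export
plant_relatedness <- function(genotypes, config) {
  config <- validate_sim_config(config)
  if (config$n_related_pairs == 0) return(genotypes)
  if (!all(c("freq", "block") %in% names(genotypes$snp_map))) {
    abort("plant_relatedness needs the simulated snp_map (freq, block).",
          class = "heritkit_config_error")
  }
  with_sim_seed(config$seed, 505L, {
    k <- config$related_kinship
    freq <- genotypes$snp_map$freq
    block <- genotypes$snp_map$block
    x <- genotypes$dosages
    share_a <- min(1, 2 * k)        # fraction of blocks sharing haplotype A
    share_b <- max(0, 2 * k - 1)    # second haplotype too when k > 0.5
    pairs <- tibble(first = 2L * seq_len(config$n_related_pairs) - 1L,
                    second = 2L * seq_len(config$n_related_pairs))
    blocks <- unique(block)
    for (p in seq_len(nrow(pairs))) {
      i1 <- pairs$first[p]; i2 <- pairs$second[p]
      hap_a <- simulate_haplotypes(1L, freq, block, config$ld_rho)[1L, ]
      hap_b <- simulate_haplotypes(1L, freq, block, config$ld_rho)[1L, ]
      sa <- blocks[runif(length(blocks)) < share_a]
      sb <- blocks[runif(length(blocks)) < share_b]
      ja <- which(block %in% sa)
      jb <- which(block %in% sb)
      if (length(ja)) hap_a[ja] <- sample_haplotype_from(x[i1, ja])
      if (length(jb)) hap_b[jb] <- sample_haplotype_from(x[i1, jb])
      x[i2, ] <- hap_a + hap_b
    }
    out <- genotype_matrix(x, genotypes$subjects, genotypes$snp_map)
    attr(out, "planted_pairs") <- pairs
    out
  })
}

# One allele per SNP consistent with the donor's dosage (het -> fair coin).
sample_haplotype_from <- function(dosage) {
  out <- as.integer(dosage >= 2)
  het <- which(dosage == 1)
  if (length(het)) out[het] <- rbinom(length(het), 1L, 0.5)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
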