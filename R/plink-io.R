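#' Read and write PLINK bed/bim/fam filesets
#'
#' The .bed file is the SNP-major 2-bit binary format (magic bytes
#' `0x6c 0x1b 0x01`): per SNP, `ceiling(n/4)` bytes, subjects packed from the
#' low bits. Two-bit codes: `00` homozygous A1 (dosage 2), `01` missing,
#' `10` heterozygous, `11` homozygous A2 (dosage 0). Dosages count copies of
#' allele A1. Round trips are lossless for hard-call data.
#'
#' @param genotypes A [genotype_matrix()] with hard calls (0/1/2/NA).
#' @param prefix Path prefix; `.bed`, `.bim` and `.fam` are appended.
#' @return `write_plink()` returns `prefix` invisibly; `read_plink()` returns
#'   a [genotype_matrix()].
#' @examples
#' g <- simulate_genotypes(sim_config(n_subjects = 5, n_snps = 8, seed = 1))
#' pre <- file.path(tempdir(), "toy")
#' write_plink(g, pre)
#' g2 <- read_plink(pre)
#' all.equal(g$dosages, g2$dosages, check.attributes = FALSE)
#' @export
write_plink <- function(genotypes, prefix) {
  x <- genotypes$dosages
  if (any(!is.na(x) & x != round(x))) {
    abort("write_plink requires hard calls (0/1/2/NA); fractional dosages found.",
          class = "heritkit_format_error")
  }
  write.table(
    data.frame(genotypes$snp_map$chrom, genotypes$snp_map$id, 0,
               genotypes$snp_map$pos, genotypes$snp_map$a1,
               genotypes$snp_map$a2),
    paste0(prefix, ".bim"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  write.table(
    data.frame(genotypes$subjects$fid, genotypes$subjects$iid, 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = " ")

  n <- nrow(x)
  code <- matrix(3L, n, ncol(x))      # hom A2 (dosage 0)
  code[!is.na(x) & x == 2] <- 0L      # hom A1
  code[!is.na(x) & x == 1] <- 2L      # het
  code[is.na(x)] <- 1L                # missing
  pad <- (-n) %% 4L
  if (pad > 0) code <- rbind(code, matrix(0L, pad, ncol(x)))
  idx <- seq(1L, nrow(code), by = 4L)
  bytes <- code[idx, , drop = FALSE] +
    4L * code[idx + 1L, , drop = FALSE] +
    16L * code[idx + 2L, , drop = FALSE] +
    64L * code[idx + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  for (ext in c(".bed", ".bim", ".fam")) {
    if (!file.exists(paste0(prefix, ext))) {
      abort(sprintf("missing file: %s", paste0(prefix, ext)),
            class = "heritkit_format_error")
    }
  }
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    colClasses = "character")
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  expected <- 3 + bytes_per_snp * m
  actual <- file.size(bed_path)
  raw <- readBin(bed_path, "raw", n = actual)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b) ||
      raw[3] != as.raw(0x01)) {
    abort(sprintf("%s: bad magic bytes at offset 0 (not a SNP-major bed file).",
                  bed_path),
          class = "heritkit_format_error")
  }
  if (actual != expected) {
    abort(sprintf(
      "%s: expected %d bytes for %d subjects x %d SNPs, found %d (offset %d).",
      bed_path, expected, n, m, actual, min(expected, actual)),
      class = "heritkit_format_error")
  }
  # 256 x 4 lookup: byte value -> four dosages (low bits = first subject)
  codes <- as.integer(raw[-(1:3)])
  lut <- sapply(0:3, function(k) {
    two_bit <- bitwAnd(bitwShiftR(0:255, 2L * k), 3L)
    c(2, NA, 1, 0)[two_bit + 1L]
  })
  dos <- matrix(t(lut[codes + 1L, , drop = FALSE]), nrow = 4L * bytes_per_snp)
  dos <- dos[seq_len(n), , drop = FALSE]
  genotype_matrix(
    dos,
    tibble(fid = fam[[1]], iid = fam[[2]]),
    tibble(id = bim$id, chrom = bim$chrom, pos = bim$pos,
           a1 = bim$a1, a2 = bim$a2)
  )
}

#' Read and write the GCTA binary GRM triple
#'
#' `prefix.grm.bin` holds the lower triangle (diagonal included, pair
#' `(j, k <= j)` in row-major order) as single-precision floats,
#' `prefix.grm.N.bin` the per-pair SNP counts in the same layout, and
#' `prefix.grm.id` the FID/IID table — the layout GCTA and its ecosystem
#' exchange.
#'
#' @param grm A [compute_grm()] result.
#' @param prefix Path prefix; `.grm.bin`, `.grm.N.bin`, `.grm.id` appended.
#' @return `write_grm()` returns `prefix` invisibly; `read_grm()` returns a
#'   `grm_result` (values are single precision after a round trip).
#' @export
write_grm <- function(grm, prefix) {
  n <- nrow(grm$values)
  lower <- which(lower.tri(grm$values, diag = TRUE), arr.ind = TRUE)
  ord <- order(lower[, "row"], lower[, "col"])
  lower <- lower[ord, , drop = FALSE]
  vals <- grm$values[lower]
  counts <- grm$pair_snp_counts[lower]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(vals), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(counts), con, size = 4)
  close(con)
  write.table(grm$subjects[, c("fid", "iid")], paste0(prefix, ".grm.id"),
              quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  ids <- read.table(paste0(prefix, ".grm.id"), header = FALSE,
                    colClasses = "character")
  n <- nrow(ids)
  n_pairs <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = n_pairs + 1,
                  size = 4)
  counts <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = n_pairs + 1,
                    size = 4)
  if (length(vals) != n_pairs || length(counts) != n_pairs) {
    abort(sprintf(
      "%s.grm.bin: expected %d float32 values for %d ids, found %d.",
      prefix, n_pairs, n, length(vals)),
      class = "heritkit_format_error")
  }
  a <- matrix(0, n, n)
  nn <- matrix(0, n, n)
  lower <- which(lower.tri(a, diag = TRUE), arr.ind = TRUE)
  ord <- order(lower[, "row"], lower[, "col"])
  lower <- lower[ord, , drop = FALSE]
  a[lower] <- vals
  nn[lower] <- counts
  a <- a + t(a) - diag(diag(a))
  nn <- nn + t(nn) - diag(diag(nn))
  new_grm_result(a, nn, tibble(fid = ids[[1]], iid = ids[[2]]),
                 n_snps_total = max(nn))
}

#' Read and write PLINK-style phenotype/covariate tables
#'
#' Whitespace-delimited files whose first two columns are FID and IID,
#' followed by one or more value columns, no header (the PLINK/GCTA
#' convention).
#'
#' @param df Data frame with columns `fid`, `iid`, then value columns.
#' @param path File path.
#' @param col_names Optional names for the value columns on read; defaults to
#'   `V1, V2, ...`.
#' @return `read_pheno()` returns a tibble with `fid`, `iid` and the value
#'   columns.
#' @export
write_pheno <- function(df, path) {
  stopifnot(all(c("fid", "iid") %in% names(df)))
  write.table(df[, c("fid", "iid", setdiff(names(df), c("fid", "iid")))],
              path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pheno
#' @export
read_pheno <- function(path, col_names = NULL) {
  tab <- read.table(path, header = FALSE, colClasses = NA)
  names(tab)[1:2] <- c("fid", "iid")
  tab$fid <- as.character(tab$fid)
  tab$iid <- as.character(tab$iid)
  if (!is.null(col_names)) {
    if (length(col_names) != ncol(tab) - 2) {
      abort("col_names length does not match value columns.",
            class = "heritkit_format_error")
    }
    names(tab)[-(1:2)] <- col_names
  }
  as_tibble(tab)
}

#' Read and write gene tables as BED
#'
#' Gene tables are held internally in BED convention (`chrom`, `start`
#' 0-based, `end` exclusive, `name`); [annotate_genic()] converts to 1-based
#' closed coordinates at its boundary. I/O goes through rtracklayer.
#'
#' @param genes Tibble with `chrom`, `start`, `end`, `name`.
#' @param path BED file path.
#' @return `read_gene_bed()` returns the gene tibble.
#' @export
write_gene_bed <- function(genes, path) {
  if (nrow(genes) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  gr <- GenomicRanges_from_bed(genes)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_gene_bed
#' @export
read_gene_bed <- function(path) {
  if (file.size(path) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  gr <- rtracklayer::import(path, format = "BED")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = as.integer(GenomicRanges::start(gr) - 1L),
         end = as.integer(GenomicRanges::end(gr)),
         name = if (!is.null(gr$name)) as.character(gr$name) else
           sprintf("region%04d", seq_along(gr)))
}

GenomicRanges_from_bed <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    name = genes$name
  )
}

#' Read and write per-SNP conservation score tables
#'
#' Tab-separated `chrom`, `pos` (1-based), `score`; missing scores are empty
#' or `NA`.
#'
#' @param scores Tibble with `chrom`, `pos`, `score` (and optionally
#'   `snp_id`, carried through).
#' @param path File path.
#' @return `read_scores_tsv()` returns the score tibble.
#' @export
write_scores_tsv <- function(scores, path) {
  keep <- intersect(c("chrom", "pos", "score"), names(scores))
  write.table(scores[, keep], path, quote = FALSE, row.names = FALSE,
              col.names = TRUE, sep = "\t")
  invisible(path)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       colClasses = c(chrom = "character")))
}

#' Read and write the transparent TSV dosage dialect
#'
#' A plain-text alternative to .bed: a header row `id` plus SNP ids, one row
#' per subject (`fid:iid` joined with `_` is avoided — the id column holds the
#' IID; FIDs equal IIDs on read unless a map is supplied).
#'
#' @param genotypes A [genotype_matrix()].
#' @param path File path.
#' @param snp_map Optional SNP map tibble on read; defaults to a synthetic
#'   single-chromosome map at 1 kb spacing.
#' @return `read_dosage_tsv()` returns a [genotype_matrix()].
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(id = genotypes$subjects$iid, genotypes$dosages,
                   check.names = FALSE)
  write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path, snp_map = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(tab[[1]])
  dos <- as.matrix(tab[, -1, drop = FALSE])
  if (is.null(snp_map)) {
    snp_map <- tibble(id = colnames(dos), chrom = "1",
                      pos = 1L + (seq_len(ncol(dos)) - 1L) * 1000L,
                      a1 = "A", a2 = "B")
  }
  genotype_matrix(dos, tibble(fid = ids, iid = ids), snp_map)
}
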