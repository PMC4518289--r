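#' Pipeline configuration
#'
#' Declarative description of an end-to-end run: either a simulation recipe
#' (a [sim_config()]) or paths to existing inputs, plus the thresholds of
#' every stage and the analysis modes to run.
#'
#' @param sim A [sim_config()] describing the synthetic cohort, or `NULL`
#'   when `genotype_prefix` points at an existing PLINK fileset.
#' @param genotype_prefix Optional PLINK prefix to ingest instead of
#'   simulating.
#' @param out_dir Output directory (created if missing); `NULL` disables
#'   file output.
#' @param modes Character subset of `c("single", "genic-partition",
#'   "conservation-partition", "twin")`.
#' @param qc Named list overriding [qc_filter()] thresholds.
#' @param grm_prune Relatedness-pruning threshold(s); both 0.025 and 0.1 can
#'   be given to mirror the dual-threshold robustness reporting.
#' @param flank_bp Genic flank for [annotate_genic()].
#' @param window_bp LD window for [compute_ld_matrix()].
#' @param n_pcs GRM principal components used as covariates.
#' @param seed Run seed (also seeds the simulation when `sim$seed` is unset).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            genotype_prefix = NULL,
                            out_dir = NULL,
                            modes = c("single", "genic-partition",
                                      "conservation-partition", "twin"),
                            qc = list(),
                            grm_prune = 0.025,
                            flank_bp = 20000,
                            window_bp = 1e6,
                            n_pcs = 10,
                            seed = 1L) {
  modes <- match.arg(modes, several.ok = TRUE)
  if (any(grm_prune <= 0)) {
    abort("grm_prune thresholds must be positive.",
          class = "heritkit_config_error")
  }
  if (n_pcs < 0) {
    abort("n_pcs must be nonnegative.", class = "heritkit_config_error")
  }
  if (!is.null(genotype_prefix) &&
      !file.exists(paste0(genotype_prefix, ".bed"))) {
    abort(sprintf("genotype fileset not found: %s.bed", genotype_prefix),
          class = "heritkit_config_error")
  }
  structure(list(sim = sim, genotype_prefix = genotype_prefix,
                 out_dir = out_dir, modes = modes, qc = qc,
                 grm_prune = grm_prune, flank_bp = flank_bp,
                 window_bp = window_bp, n_pcs = n_pcs,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the `sim` block
#' holds [sim_config()] fields.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- if (!is.null(raw$sim)) do.call(sim_config, raw$sim) else sim_config()
  args <- raw[setdiff(names(raw), "sim")]
  do.call(pipeline_config, c(list(sim = sim), args))
}

#' Run the heritability pipeline end to end
#'
#' Simulate (or ingest) genotypes, apply QC, compute the GRM, prune cryptic
#' relatedness at each configured threshold, extract ancestry principal
#' components, annotate SNPs (genic/intergenic and LD-weighted conservation
#' with a median split), fit the GREML models for every requested mode, and
#' fit the twin ACE model. Every stage appends a provenance record (inputs,
#' parameters, counts, content hashes of written files).
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `reports` (named list of
#'   `h2_report` tibbles per mode and prune threshold), `twin` (the
#'   `ace_fit` and correlations, when requested), `qc`, `pruning`, `log`
#'   (tibble of stage records), `score_correlation` (genic-vs-conservation
#'   LD-weighted score correlation, when both annotations were built).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  t0 <- Sys.time()
  note <- function(stage, ...) {
    fields <- list(...)
    log[[length(log) + 1]] <<- tibble(
      time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      stage = stage,
      detail = paste(names(fields), vapply(fields, as.character, ""),
                     sep = "=", collapse = " "))
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(writer, obj, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    writer(obj, path)
    note("write", file = name, md5 = unname(tools::md5sum(path)))
  }

  sim <- config$sim
  if (!is.null(sim) && is.null(sim$seed)) sim$seed <- config$seed

  ## genotypes
  if (!is.null(config$genotype_prefix)) {
    geno <- read_plink(config$genotype_prefix)
    note("ingest", prefix = config$genotype_prefix,
         n = nrow(geno$dosages), m = ncol(geno$dosages))
  } else {
    geno <- simulate_genotypes(sim)
    if (sim$n_related_pairs > 0) geno <- plant_relatedness(geno, sim)
    note("simulate", n = nrow(geno$dosages), m = ncol(geno$dosages),
         seed = sim$seed)
  }

  ## QC
  qc_args <- utils::modifyList(
    list(miss_max = 0.05, maf_min = 0.01, hwe_alpha = 1e-6, het_sd = 5),
    config$qc)
  qc <- do.call(qc_filter, c(list(geno), qc_args))
  geno <- qc$genotypes
  note("qc", samples = qc$counts$after[1], snps = qc$counts$after[2],
       removed = nrow(qc$report))
  if (!is.null(out_dir)) emit(write_qc_report, qc, "qc_report.tsv")

  ## annotation (simulated alongside the genotypes)
  ann <- NULL
  need_annotation <- !is.null(sim) &&
    any(config$modes %in% c("genic-partition", "conservation-partition"))
  if (need_annotation) {
    ann <- simulate_annotation(geno$snp_map, sim)
    if (!is.null(out_dir)) {
      emit(write_gene_bed, ann$genes, "genes.bed")
      emit(write_scores_tsv,
           mutate(ann$scores, snp_id = NULL, genic = NULL), "conservation.tsv")
    }
    note("annotate", genes = nrow(ann$genes),
         scored = sum(!is.na(ann$scores$score)))
  }

  ## GRM + pruning + PCA, then model fits per prune threshold
  grm <- compute_grm(geno)
  note("grm", n = nrow(grm$values), snps = grm$n_snps_total)
  if (!is.null(out_dir)) {
    write_grm(grm, file.path(out_dir, "cohort"))
    note("write", file = "cohort.grm.bin",
         md5 = unname(tools::md5sum(file.path(out_dir, "cohort.grm.bin"))))
  }

  pheno <- NULL
  if (!is.null(sim) && any(config$modes != "twin")) {
    ann_cat <- if (!is.null(ann)) {
      tibble(snp_id = ann$scores$snp_id,
             category = ifelse(ann$scores$genic, "genic", "intergenic"))
    } else NULL
    psim <- simulate_phenotype(geno, ann_cat, sim)
    pheno <- psim$phenotypes
    note("phenotype", n = nrow(pheno),
         h2_realized = sprintf("%.4f", psim$h2_realized))
    if (!is.null(out_dir)) {
      emit(function(obj, path) write_pheno(obj[, c("fid", "iid", "y")], path),
           pheno, "phenotype.phen")
    }
  }

  reports <- list()
  pruning <- list()
  for (thr in config$grm_prune) {
    kept <- prune_related(grm, thr)
    keep_idx <- match(kept, geno$subjects$iid)
    pruning[[as.character(thr)]] <- tibble(
      threshold = thr, kept = length(kept),
      removed = nrow(geno$subjects) - length(kept))
    note("prune", threshold = thr, kept = length(kept))
    g_thr <- subset_genotypes(geno, subjects = keep_idx)
    # pruning can leave SNPs monomorphic in the retained subset
    p_thr <- colMeans(g_thr$dosages, na.rm = TRUE) / 2
    poly <- which(p_thr > 0 & p_thr < 1)
    if (length(poly) < ncol(g_thr$dosages)) {
      note("prune_snps", threshold = thr,
           dropped_monomorphic = ncol(g_thr$dosages) - length(poly))
      g_thr <- subset_genotypes(g_thr, snps = poly)
    }
    if (is.null(pheno)) next
    ph_thr <- pheno[match(kept, pheno$iid), , drop = FALSE]
    covs <- ph_thr[, c("fid", "iid", "age", "sex", "cohort")]

    for (mode in setdiff(config$modes, "twin")) {
      partition <- NULL
      if (mode == "genic-partition") {
        track <- annotate_genic(g_thr$snp_map, ann$genes,
                                flank_bp = config$flank_bp)
        partition <- build_partition(track)
      } else if (mode == "conservation-partition") {
        ld <- compute_ld_matrix(g_thr, window_bp = config$window_bp)
        raw <- tibble(snp_id = g_thr$snp_map$id,
                      score = ann$scores$score[
                        match(g_thr$snp_map$id, ann$scores$snp_id)])
        weighted <- ld_weight_scores(ld, raw)
        split <- median_split(weighted)
        partition <- build_partition(split)
      }
      rep_name <- sprintf("%s_grm%s", mode, thr)
      res <- estimate_h2(g_thr, ph_thr[, c("fid", "iid", "y")],
                         covariates = covs, partition = partition,
                         n_pcs = config$n_pcs)
      reports[[rep_name]] <- res
      note("reml", mode = mode, threshold = thr,
           loglik = sprintf("%.4f", res$loglik[1]))
      if (!is.null(out_dir)) {
        emit(write_hsq_tsv, res, sprintf("%s.hsq.tsv", rep_name))
      }
    }
  }

  ## annotation-score correlation (genic vs conservation, LD-weighted)
  score_cor <- NULL
  if (!is.null(ann) &&
      all(c("genic-partition", "conservation-partition") %in% config$modes)) {
    ld <- compute_ld_matrix(geno, window_bp = config$window_bp)
    genic_track <- tibble(snp_id = geno$snp_map$id,
                          score = as.numeric(ann$scores$genic))
    cons_track <- tibble(snp_id = geno$snp_map$id,
                         score = ann$scores$score)
    wg <- ld_weight_scores(ld, genic_track)
    wc <- ld_weight_scores(ld, cons_track)
    score_cor <- score_correlation(wg, wc)
    note("score_correlation", r = sprintf("%.4f", score_cor$r))
  }

  ## twin arm
  twin <- NULL
  if ("twin" %in% config$modes && !is.null(sim)) {
    tw <- simulate_twins(sim)
    twin <- list(correlations = twin_correlations(tw), fit = fit_ace(tw))
    note("twin", r_mz = sprintf("%.4f", twin$correlations$r_mz),
         r_dz = sprintf("%.4f", twin$correlations$r_dz))
  }

  log_tbl <- bind_rows(log)
  if (!is.null(out_dir)) {
    write.table(log_tbl, file.path(out_dir, "pipeline_log.tsv"),
                quote = FALSE, row.names = FALSE, sep = "\t")
  }
  note("done", seconds = sprintf("%.1f", as.numeric(Sys.time() - t0,
                                                    units = "secs")))
  structure(list(reports = reports, twin = twin, qc = qc,
                 pruning = bind_rows(pruning), log = bind_rows(log),
                 score_correlation = score_cor, config = config),
            class = "pipeline_result")
}

#' Summarize pipeline fits with significance stars
#'
#' Per-phenotype/component table of estimates, standard errors and
#' likelihood-ratio p-values, starred at the nominal level and at the
#' Bonferroni threshold `alpha / n_phenotypes`.
#'
#' @param result A `pipeline_result` (or a single `h2_report`).
#' @param alpha Nominal significance level.
#' @return Tibble with `mode`, `phenotype`, `component`, `estimate`, `se`,
#'   `p_value`, `stars`; the Bonferroni threshold is in
#'   `attr(, "bonferroni")`.
#' @export
report_heritability <- function(result, alpha = 0.05) {
  reports <- if (inherits(result, "pipeline_result")) result$reports else
    list(report = result)
  rows <- imap(reports, function(rep, nm) {
    df <- rep[rep$component != "residual", , drop = FALSE]
    tibble(mode = nm, phenotype = df$phenotype, component = df$component,
           estimate = df$prop, se = df$prop_se, p_value = df$p_value)
  })
  out <- bind_rows(rows)
  n_tests <- max(1, length(unique(out$phenotype)))
  bonf <- alpha / n_tests
  out$stars <- ifelse(is.na(out$p_value), "",
                      ifelse(out$p_value < bonf, "**",
                             ifelse(out$p_value < alpha, "*", "")))
  attr(out, "bonferroni") <- signif(bonf, 2)
  out
}

#' Write a pipeline summary as JSON and TSV
#'
#' @param summary Tibble from [report_heritability()].
#' @param prefix Output path prefix (`.json` and `.tsv` appended).
#' @export
write_report <- function(summary, prefix) {
  write.table(as.data.frame(summary), paste0(prefix, ".tsv"),
              quote = FALSE, row.names = FALSE, sep = "\t")
  jsonlite::write_json(as.data.frame(summary), paste0(prefix, ".json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(prefix)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d model report(s)\n", length(x$reports)))
  if (length(x$reports)) print(report_heritability(x))
  if (!is.null(x$twin)) {
    cat(sprintf("twin: rMZ = %.3f, rDZ = %.3f, a2 = %.3f\n",
                x$twin$correlations$r_mz, x$twin$correlations$r_dz,
                x$twin$fit$a2))
  }
  invisible(x)
}
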