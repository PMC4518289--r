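#' Weighted-average regional values from vertex measures
#'
#' Collapses vertex-level surface-area measures to regional phenotypes using
#' partial parcel memberships: region value
#' `sum_v w_vr area_v / sum_v w_vr` (weighted average; `stat = "sum"` gives
#' the weighted sum instead, which interacts differently with global
#' normalization).
#'
#' @param vertex_areas n x V matrix of per-subject vertex areas (or a vector
#'   for one subject).
#' @param weights V x R membership matrix, entries in `[0, 1]`; each
#'   vertex's memberships may sum to at most 1. Column names name the
#'   regions.
#' @param stat `"average"` (default) or `"sum"`.
#' @return n x R matrix (tibble) of regional values.
#' @examples
#' parcel_area(c(2, 4, 8, 8), matrix(c(0.5, 0.5, 0, 0), ncol = 1))
#' @export
parcel_area <- function(vertex_areas, weights, stat = c("average", "sum")) {
  stat <- match.arg(stat)
  if (is.vector(vertex_areas)) vertex_areas <- matrix(vertex_areas, nrow = 1)
  weights <- as.matrix(weights)
  if (ncol(vertex_areas) != nrow(weights)) {
    abort("vertex count does not match the weight matrix.",
          class = "heritkit_format_error")
  }
  wsum <- colSums(weights)
  if (any(wsum <= 0)) {
    abort(sprintf("region(s) with zero total weight: %s",
                  paste(which(wsum <= 0), collapse = ", ")),
          class = "heritkit_format_error")
  }
  if (any(rowSums(weights) > 1 + 1e-8)) {
    abort("vertex memberships must sum to at most 1.",
          class = "heritkit_format_error")
  }
  out <- vertex_areas %*% weights
  if (stat == "average") out <- sweep(out, 2, wsum, "/")
  colnames(out) <- colnames(weights) %||%
    sprintf("region%02d", seq_len(ncol(weights)))
  as_tibble(out)
}

#' Normalize regional values by total surface area
#'
#' Divides each subject's regional measures by that subject's total surface
#' area so downstream genetic effects are region-specific rather than global.
#'
#' @param region_values n x R matrix/tibble of regional areas.
#' @param total_area Length-n vector of total surface areas (must be
#'   positive).
#' @return Normalized values, same shape as `region_values`.
#' @export
normalize_global <- function(region_values, total_area) {
  if (any(total_area <= 0)) {
    abort("total_area must be positive for every subject.",
          class = "heritkit_format_error")
  }
  out <- sweep(as.matrix(region_values), 1, total_area, "/")
  if (is.null(colnames(out))) {
    colnames(out) <- sprintf("region%02d", seq_len(ncol(out)))
  }
  as_tibble(out)
}

#' Residualize phenotypes on covariates with a smooth age term
#'
#' Ordinary least-squares residual after regressing on a natural cubic
#' spline basis of age (`age_basis_df` degrees of freedom), sex, the
#' age-spline-by-sex interaction, and categorical indicators for any of
#' `scanner`, `diagnosis`, `cohort` present in the covariate table. The
#' spline nests the linear trend, so a purely linear age effect is removed
#' exactly; the default 4 df absorbs the kind of lifespan curvature seen in
#' samples spanning childhood to old age.
#'
#' @param values Numeric vector, or n x R matrix/tibble of phenotypes.
#' @param covariates Tibble with `age` and `sex` (0/1 or factor) plus
#'   optional `scanner`, `diagnosis`, `cohort` columns.
#' @param age_basis_df Degrees of freedom of the natural-spline age basis.
#' @return Residuals in the input shape, with the design column names in
#'   `attr(, "design")`.
#' @export
residualize <- function(values, covariates, age_basis_df = 4) {
  vec_in <- is.null(dim(values))
  vmat <- as.matrix(values)
  n <- nrow(vmat)
  if (n != nrow(covariates)) {
    abort("values and covariates disagree on subject count.",
          class = "heritkit_format_error")
  }
  df <- as.data.frame(covariates)
  if (!all(c("age", "sex") %in% names(df))) {
    abort("covariates must include age and sex.",
          class = "heritkit_format_error")
  }
  df$sex <- if (is.numeric(df$sex)) factor(df$sex) else factor(df$sex)
  for (f in intersect(c("scanner", "diagnosis", "cohort"), names(df))) {
    df[[f]] <- factor(df[[f]])
  }
  terms <- c(sprintf("splines::ns(age, df = %d) * sex", age_basis_df),
             intersect(c("scanner", "diagnosis", "cohort"), names(df)))
  design <- model.matrix(
    stats::as.formula(paste("~", paste(terms, collapse = " + "))), data = df)
  if (n < ncol(design) + 2) {
    abort("too few subjects for the covariate design.",
          class = "heritkit_config_error")
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    abort(sprintf("rank-deficient covariate design; aliased columns: %s",
                  paste(aliased, collapse = ", ")),
          class = "heritkit_format_error")
  }
  res <- qr.resid(qrd, vmat)
  if (vec_in) res <- drop(res)
  attr(res, "design") <- colnames(design)
  res
}

#' Prepare adjusted regional phenotypes from vertex data
#'
#' Convenience chain: [parcel_area()] then [normalize_global()] then
#' [residualize()], returning a PLINK-style phenotype tibble ready for
#' [estimate_h2()].
#'
#' @param vertex_areas n x V vertex-area matrix.
#' @param weights V x R parcel membership matrix.
#' @param covariates Covariate tibble with `fid`, `iid`, `age`, `sex`, and
#'   optional `scanner`/`diagnosis`/`cohort`.
#' @param total_area Optional per-subject total surface area; defaults to the
#'   subject's vertex-area sum.
#' @param age_basis_df Passed to [residualize()].
#' @return Tibble with `fid`, `iid` and one adjusted column per region.
#' @export
prepare_phenotypes <- function(vertex_areas, weights, covariates,
                               total_area = NULL, age_basis_df = 4) {
  regional <- parcel_area(vertex_areas, weights)
  total_area <- total_area %||% rowSums(as.matrix(vertex_areas))
  normed <- normalize_global(regional, total_area)
  adj <- residualize(normed, covariates, age_basis_df = age_basis_df)
  out <- bind_cols(tibble(fid = covariates$fid, iid = covariates$iid),
                   as_tibble(as.matrix(adj)))
  out
}
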