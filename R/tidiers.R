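#' Tidy a GREML fit
#'
#' One row per variance component with estimates, standard errors and
#' variance proportions.
#'
#' @param x A `greml_fit`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `sigma2`, `se`, `prop`,
#'   `prop_se`.
#' @method tidy greml_fit
#' @export
tidy.greml_fit <- function(x, ...) x$components

#' @rdname tidy.greml_fit
#' @return `glance()` returns a one-row tibble: `loglik`, `iterations`,
#'   `converged`, `n`, `p`, `method`.
#' @method glance greml_fit
#' @export
glance.greml_fit <- function(x, ...) {
  tibble(loglik = x$loglik, iterations = x$iterations,
         converged = x$converged, n = x$n, p = x$p, method = x$method)
}

#' Tidy an ACE twin-model fit
#'
#' @param x An `ace_fit`.
#' @param ... Unused.
#' @return One row per standardized component (`a2`, `c2`, `e2`) with
#'   `estimate` and `se`.
#' @method tidy ace_fit
#' @export
tidy.ace_fit <- function(x, ...) {
  tibble(component = c("a2", "c2", "e2"),
         estimate = c(x$a2, x$c2, x$e2),
         se = unname(x$se))
}

#' @rdname tidy.ace_fit
#' @return `glance()` returns a one-row tibble with the fit summary and
#'   implied twin correlations.
#' @method glance ace_fit
#' @export
glance.ace_fit <- function(x, ...) {
  tibble(minus2ll = x$minus2ll, r_mz = x$r_mz, r_dz = x$r_dz,
         n_mz = x$n_mz, n_dz = x$n_dz, converged = x$converged)
}

#' Bar chart of variance proportions from a GREML fit
#'
#' Proportions of phenotypic variance per component with one-standard-error
#' bars, the conventional display for heritability partitions.
#'
#' @param object A `greml_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot greml_fit
#' @export
autoplot.greml_fit <- function(object, ...) {
  df <- object$components
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$prop)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$prop - .data$prop_se),
                   ymax = pmin(1, .data$prop + .data$prop_se)),
      width = 0.2) +
    ggplot2::labs(x = NULL, y = "proportion of phenotypic variance") +
    ggplot2::theme_minimal()
}

#' Stacked ACE decomposition plot
#'
#' @param object An `ace_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ace_fit
#' @export
autoplot.ace_fit <- function(object, ...) {
  df <- tidy.ace_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(x = "ACE", y = .data$estimate,
                                   fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "standardized variance component") +
    ggplot2::theme_minimal()
}

#' Heritability estimates per phenotype with error bars
#'
#' Mirrors the usual regional-heritability figure: one bar per phenotype and
#' component with one-standard-error bars and significance stars at the
#' nominal and multiplicity-corrected thresholds.
#'
#' @param report An `h2_report` from [estimate_h2()] or [run_pipeline()].
#' @param alpha Nominal significance level.
#' @return A ggplot object.
#' @export
plot_heritability <- function(report, alpha = 0.05) {
  df <- report[report$component != "residual", , drop = FALSE]
  n_pheno <- length(unique(df$phenotype))
  bonf <- alpha / max(1, n_pheno)
  df$stars <- ifelse(!is.na(df$p_value) & df$p_value < bonf, "**",
                     ifelse(!is.na(df$p_value) & df$p_value < alpha, "*", ""))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phenotype, y = .data$prop,
                                   fill = .data$component)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$prop - .data$prop_se),
                   ymax = pmin(1, .data$prop + .data$prop_se)),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25) +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$stars,
                   y = pmin(1, .data$prop + .data$prop_se) + 0.02),
      position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::labs(x = NULL, y = "variance proportion (h2)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
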