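#' Restricted log-likelihood of a GRM mixed model
#'
#' For `V = sum_c G_c sigma2_c + I sigma2_e`, returns the full REML
#' log-likelihood of an orthonormal error-contrast basis,
#' `-1/2 [log|V| + log|X'V^-1 X| - log|X'X| + y'Py + (n-p) log 2pi]` with
#' `P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1`. This convention equals the
#' multivariate-normal log-density of the contrasts exactly (no dropped
#' constants), so independent dense evaluations agree to machine precision.
#'
#' @param y Phenotype vector (length n).
#' @param X Fixed-effects design matrix (n x p, full column rank, including
#'   the intercept).
#' @param grms List of n x n genetic relationship matrices (or a single
#'   matrix).
#' @param sigma2 Variance components, genetic components first, residual
#'   last (length `length(grms) + 1`), all nonnegative.
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(y, X, grms, sigma2) {
  if (is.matrix(grms)) grms <- list(grms)
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (length(sigma2) != length(grms) + 1) {
    abort("sigma2 must have one entry per GRM plus the residual.",
          class = "heritkit_config_error")
  }
  v <- diag(sigma2[length(sigma2)], n)
  for (k in seq_along(grms)) v <- v + sigma2[k] * grms[[k]]
  ch <- tryCatch(chol(v), error = function(e) {
    abort("V is singular or not positive definite; add jitter or constrain components.",
          class = "heritkit_singular_error")
  })
  logdet_v <- 2 * sum(log(diag(ch)))
  vinv_y <- backsolve(ch, forwardsolve(t(ch), y))
  vinv_x <- backsolve(ch, forwardsolve(t(ch), X))
  xtvx <- crossprod(X, vinv_x)
  ch2 <- chol(xtvx)
  logdet_xtvx <- 2 * sum(log(diag(ch2)))
  logdet_xtx <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  beta_part <- backsolve(ch2, forwardsolve(t(ch2), crossprod(X, vinv_y)))
  ypy <- sum(y * vinv_y) - sum(crossprod(X, vinv_y) * beta_part)
  -0.5 * (logdet_v + logdet_xtvx - logdet_xtx + ypy + (n - p) * log(2 * pi))
}

# ---- REML backends -------------------------------------------------------
# A backend maps sigma2 -> list(loglik, q = y'P G_k P y, t = tr(P G_k),
# ai = average-information matrix), indices covering the genetic components
# then the residual.

make_dense_backend <- function(y, X, grms) {
  n <- length(y); p <- ncol(X)
  logdet_xtx <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  gs <- c(grms, list(diag(1, n)))
  nc <- length(gs)
  function(sigma2) {
    v <- diag(sigma2[nc], n)
    for (k in seq_len(nc - 1)) v <- v + sigma2[k] * gs[[k]]
    ch <- chol(v)
    vinv <- chol2inv(ch)
    vinv_x <- vinv %*% X
    xtvx <- crossprod(X, vinv_x)
    b <- solve(xtvx)
    pmat <- vinv - vinv_x %*% b %*% t(vinv_x)
    py <- drop(pmat %*% y)
    u <- vector("list", nc)
    q <- t <- numeric(nc)
    for (k in seq_len(nc)) {
      u[[k]] <- if (k < nc) drop(gs[[k]] %*% py) else py
      q[k] <- sum(py * u[[k]])
      t[k] <- if (k < nc) sum(pmat * gs[[k]]) else sum(diag(pmat))
    }
    ai <- matrix(0, nc, nc)
    for (k in seq_len(nc)) {
      pu_k <- drop(pmat %*% u[[k]])
      for (l in k:nc) {
        ai[k, l] <- ai[l, k] <- 0.5 * sum(u[[l]] * pu_k)
      }
    }
    logdet_v <- 2 * sum(log(diag(ch)))
    logdet_xtvx <- as.numeric(determinant(xtvx, logarithm = TRUE)$modulus)
    ypy <- sum(y * py)
    ll <- -0.5 * (logdet_v + logdet_xtvx - logdet_xtx + ypy +
                    (n - p) * log(2 * pi))
    list(loglik = ll, q = q, t = t, ai = ai)
  }
}

# Single-GRM backend in the GRM eigenbasis: V is diagonal after rotation, so
# every per-iteration quantity is O(n p^2).
make_spectral_backend <- function(y, X, grm) {
  es <- eigen(grm, symmetric = TRUE)
  d <- es$values
  yt <- drop(crossprod(es$vectors, y))
  xt <- crossprod(es$vectors, X)
  n <- length(y); p <- ncol(X)
  logdet_xtx <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  function(sigma2) {
    vdiag <- sigma2[1] * d + sigma2[2]
    if (any(vdiag <= 0)) {
      abort("V is singular or not positive definite; add jitter or constrain components.",
            class = "heritkit_singular_error")
    }
    w <- 1 / vdiag
    wx <- w * xt
    xtvx <- crossprod(xt, wx)
    b <- solve(xtvx)
    pvec <- function(v) {                  # P %*% v in the rotated basis
      wv <- w * v
      wv - wx %*% (b %*% crossprod(xt, wv))
    }
    py <- drop(pvec(yt))
    u1 <- d * py                            # G P y
    q <- c(sum(py * u1), sum(py * py))
    qx_g <- crossprod(xt, (w^2 * d) * xt)   # X' V^-1 G V^-1 X
    qx_i <- crossprod(xt, w^2 * xt)
    t <- c(sum(w * d) - sum(b * qx_g), sum(w) - sum(b * qx_i))
    pu1 <- drop(pvec(u1))
    ai <- matrix(0, 2, 2)
    ai[1, 1] <- 0.5 * sum(u1 * pu1)
    ai[1, 2] <- ai[2, 1] <- 0.5 * sum(py * pu1)
    ai[2, 2] <- 0.5 * sum(py * drop(pvec(py)))
    logdet_v <- sum(log(vdiag))
    logdet_xtvx <- as.numeric(determinant(xtvx, logarithm = TRUE)$modulus)
    ll <- -0.5 * (logdet_v + logdet_xtvx - logdet_xtx + sum(yt * py) +
                    (n - p) * log(2 * pi))
    list(loglik = ll, q = q, t = t, ai = ai)
  }
}

#' Fit variance components by AI-REML
#'
#' Average-information REML with EM-REML for the first two iterations (for
#' stability far from the optimum). Components are kept nonnegative by
#' flooring; a component that presses against zero repeatedly is fixed at
#' zero and the remaining components are refitted. Convergence is declared
#' when the restricted log-likelihood changes by less than `tol`. Models with
#' a single GRM are fitted in the GRM eigenbasis (identical estimates,
#' much cheaper iterations); multi-component models use dense linear algebra.
#'
#' @inheritParams reml_loglik
#' @param init Optional starting values (genetic components then residual);
#'   default `var(y)/(2 * n_components)` per genetic component and
#'   `var(y)/2` residual.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Iteration cap; non-convergence is flagged, not an error.
#' @param component_names Optional names for the genetic components.
#' @return Object of class `greml_fit`: `components` tibble (component,
#'   `sigma2`, `se`, `prop` = sigma2 / total with delta-method `prop_se`),
#'   `sigma2` (named vector incl. residual), `loglik`, `iterations`,
#'   `converged`, `n`, `p`, `method`.
#' @examples
#' cfg <- sim_config(n_subjects = 150, n_snps = 600, h2_total = 0.5, seed = 2)
#' g <- simulate_genotypes(cfg)
#' ph <- simulate_phenotype(g, config = cfg)
#' grm <- compute_grm(g)
#' fit <- reml_fit(ph$phenotypes$y, cbind(1, ph$phenotypes$age), grm$values)
#' fit$components
#' @export
reml_fit <- function(y, X, grms, init = NULL, tol = 1e-8, max_iter = 100,
                     component_names = NULL) {
  if (is.matrix(grms)) grms <- list(grms)
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) {
    abort("fixed-effects design is rank deficient.",
          class = "heritkit_config_error")
  }
  nc <- length(grms) + 1
  names_all <- c(component_names %||% (names(grms) %||%
                                         paste0("G", seq_along(grms))),
                 "residual")
  vy <- var(y)
  sigma2 <- init %||% c(rep(vy / (2 * (nc - 1)), nc - 1), vy / 2)
  backend <- if (length(grms) == 1) {
    make_spectral_backend(y, X, grms[[1]])
  } else {
    make_dense_backend(y, X, grms)
  }
  method <- if (length(grms) == 1) "ai-reml (spectral)" else "ai-reml (dense)"

  floor_val <- 1e-8 * vy
  fixed <- rep(FALSE, nc)
  at_floor_count <- rep(0L, nc)
  st <- backend(sigma2)
  ll_prev <- st$loglik
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    score <- 0.5 * (st$q - st$t)
    free <- which(!fixed)
    if (iter <= 2) {
      delta <- sigma2^2 * (st$q - st$t) / n
    } else {
      delta <- rep(0, nc)
      sol <- tryCatch(solve(st$ai[free, free, drop = FALSE], score[free]),
                      error = function(e) NULL)
      if (is.null(sol)) {
        delta[free] <- sigma2[free]^2 * (st$q[free] - st$t[free]) / n
      } else delta[free] <- sol
    }
    delta[fixed] <- 0
    new_sigma2 <- sigma2 + delta
    # step-halve if the proposed point is infeasible or drops the likelihood
    for (half in 1:6) {
      cand <- sigma2 + delta / 2^(half - 1)
      cand[seq_len(nc - 1)] <- pmax(cand[seq_len(nc - 1)], floor_val)
      cand[fixed] <- 0
      cand[nc] <- max(cand[nc], floor_val)
      st_new <- tryCatch(backend(cand), error = function(e) NULL)
      if (!is.null(st_new) && is.finite(st_new$loglik) &&
          (half == 6 || st_new$loglik >= ll_prev - 1e-4)) break
    }
    if (is.null(st_new)) {
      converged <- FALSE
      break
    }
    sigma2 <- cand
    # components pinned to the floor that still want to shrink get fixed at 0
    for (k in seq_len(nc - 1)) {
      if (!fixed[k] && sigma2[k] <= floor_val * 1.0001 &&
          0.5 * (st_new$q[k] - st_new$t[k]) < 0) {
        at_floor_count[k] <- at_floor_count[k] + 1L
        if (at_floor_count[k] >= 2L) {
          fixed[k] <- TRUE
          sigma2[k] <- 0
          st_new <- backend(sigma2)
        }
      } else at_floor_count[k] <- 0L
    }
    st <- st_new
    if (abs(st$loglik - ll_prev) < tol) {
      converged <- TRUE
      ll_prev <- st$loglik
      break
    }
    ll_prev <- st$loglik
  }

  cov_mat <- tryCatch(solve(st$ai), error = function(e) {
    es <- eigen(st$ai, symmetric = TRUE)
    keep <- es$values > max(es$values) * 1e-10
    es$vectors[, keep, drop = FALSE] %*%
      (t(es$vectors[, keep, drop = FALSE]) / es$values[keep])
  })
  se <- sqrt(pmax(0, diag(cov_mat)))
  total <- sum(sigma2)
  prop <- sigma2 / total
  prop_se <- vapply(seq_len(nc), function(k) {
    grad <- -sigma2[k] / total^2 + (seq_len(nc) == k) / total
    sqrt(max(0, drop(t(grad) %*% cov_mat %*% grad)))
  }, numeric(1))

  structure(list(
    components = tibble(component = names_all, sigma2 = sigma2, se = se,
                        prop = prop, prop_se = prop_se),
    sigma2 = setNames(sigma2, names_all),
    loglik = st$loglik,
    iterations = iter,
    converged = converged,
    fixed_at_zero = names_all[fixed],
    n = n, p = p, method = method
  ), class = "greml_fit")
}

#' REML fit of the no-genetic-component (fixed effects only) model
#'
#' Closed form: the residual variance is `RSS / (n - p)` and the restricted
#' log-likelihood is `-(n - p)/2 (log sigma2_e + 1 + log 2pi)` — the reduced
#' model of the heritability likelihood-ratio test.
#'
#' @inheritParams reml_loglik
#' @return A `greml_fit` with a single residual component.
#' @export
reml_null <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  qrx <- qr(X)
  rss <- sum(qr.resid(qrx, y)^2)
  s2 <- rss / (n - p)
  ll <- -0.5 * (n - p) * (log(s2) + 1 + log(2 * pi))
  structure(list(
    components = tibble(component = "residual", sigma2 = s2,
                        se = s2 * sqrt(2 / (n - p)), prop = 1, prop_se = 0),
    sigma2 = c(residual = s2),
    loglik = ll, iterations = 0L, converged = TRUE,
    fixed_at_zero = character(), n = n, p = p, method = "closed form"
  ), class = "greml_fit")
}

#' @export
print.greml_fit <- function(x, ...) {
  cat(sprintf("<greml_fit> %s | logL = %.4f | %d iterations%s\n",
              x$method, x$loglik, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  print(x$components)
  invisible(x)
}

#' Likelihood-ratio test between nested variance-component models
#'
#' The statistic is `2 (logL_full - logL_reduced)` (small negatives clipped
#' to zero). Dropping one variance component pins it to the boundary of its
#' parameter space, so the default null is the 50:50 mixture
#' `0.5 chi2_0 + 0.5 chi2_1`; dropping `q > 1` components falls back to a
#' conservative `chi2_q` with a warning. `mixture = FALSE` forces the plain
#' chi-square.
#'
#' @param full,reduced `greml_fit` objects (or bare log-likelihoods).
#' @param df_dropped Number of variance components dropped; inferred from the
#'   fits when possible.
#' @param mixture Use the boundary mixture null for `df_dropped = 1`.
#' @return List of class `lrt_result`: `statistic`, `df_dropped`, `p_value`.
#' @examples
#' # statistic 2.706 sits at the one-sided 5% point of the mixture null
#' lrt(2.706 / 2, 0)$p_value
#' @export
lrt <- function(full, reduced, df_dropped = NULL, mixture = TRUE) {
  ll_full <- if (inherits(full, "greml_fit")) full$loglik else as.numeric(full)
  ll_red <- if (inherits(reduced, "greml_fit")) reduced$loglik else
    as.numeric(reduced)
  if (is.null(df_dropped)) {
    df_dropped <- if (inherits(full, "greml_fit") &&
                      inherits(reduced, "greml_fit")) {
      max(1L, nrow(full$components) - nrow(reduced$components))
    } else 1L
  }
  stat <- 2 * (ll_full - ll_red)
  if (stat < -1e-6) {
    abort(sprintf(
      "reduced log-likelihood exceeds the full model by %.3g: fit failure.",
      -stat / 2), class = "heritkit_fit_error")
  }
  stat <- max(0, stat)
  p <- if (df_dropped == 1 && mixture) {
    0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    if (df_dropped > 1 && mixture) {
      warn(sprintf(
        "dropping %d components: using a conservative chi-square(%d) null.",
        df_dropped, df_dropped))
    }
    pchisq(stat, df = df_dropped, lower.tail = FALSE)
  }
  structure(list(statistic = stat, df_dropped = df_dropped, p_value = p),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: statistic = %.4f (df dropped = %d), p = %.4g\n",
              x$statistic, x$df_dropped, x$p_value))
  invisible(x)
}

#' Estimate SNP heritability, optionally partitioned by annotation
#'
#' End-to-end single-cohort GREML: builds one GRM per partition category (or
#' one genome-wide GRM), appends the top GRM eigenvectors to the covariates
#' as ancestry controls, fits the full model and, per genetic component, the
#' reduced model without it, and reports variance proportions with
#' likelihood-ratio tests. Multiple phenotype columns are fitted
#' independently.
#'
#' @param genotypes A post-QC [genotype_matrix()].
#' @param phenotype Tibble with `fid`, `iid` and one or more numeric
#'   phenotype columns.
#' @param covariates Optional tibble with `fid`, `iid` and covariate columns
#'   (factors/characters are expanded to indicators).
#' @param partition Optional named list of SNP id sets (see
#'   [build_partition()]); one GRM per category.
#' @param n_pcs Number of GRM principal components appended as covariates.
#' @return Tibble of class `h2_report`: one row per phenotype x component
#'   (`sigma2`, `se`, `prop`, `prop_se`, `loglik`, `lrt_stat`, `p_value`,
#'   `converged`), with the fitted objects in `attr(, "fits")`.
#' @export
estimate_h2 <- function(genotypes, phenotype, covariates = NULL,
                        partition = NULL, n_pcs = 10) {
  iids <- genotypes$subjects$iid
  idx <- match(iids, phenotype$iid)
  if (anyNA(idx)) {
    abort("phenotype table is missing some genotyped subjects.",
          class = "heritkit_format_error")
  }
  pheno <- phenotype[idx, , drop = FALSE]
  pheno_cols <- setdiff(names(pheno), c("fid", "iid"))
  pheno_cols <- pheno_cols[vapply(pheno[pheno_cols], is.numeric, logical(1))]
  if (length(pheno_cols) == 0) {
    abort("no numeric phenotype columns found.",
          class = "heritkit_format_error")
  }

  if (is.null(partition)) {
    grms <- list(genetic = compute_grm(genotypes)$values)
    grm_all <- grms[[1]]
  } else {
    snp_ids <- genotypes$snp_map$id
    grms <- imap(partition, function(ids, nm) {
      j <- match(ids, snp_ids)
      if (anyNA(j)) {
        abort(sprintf("partition '%s' names unknown SNPs.", nm),
              class = "heritkit_format_error")
      }
      compute_grm(subset_genotypes(genotypes, snps = j))$values
    })
    m_per <- lengths(partition)
    grm_all <- Reduce(`+`, map2(grms, as.list(m_per), function(a, m) a * m)) /
      sum(m_per)
  }

  x_cov <- matrix(1, nrow(pheno), 1, dimnames = list(NULL, "intercept"))
  if (!is.null(covariates)) {
    cidx <- match(iids, covariates$iid)
    if (anyNA(cidx)) {
      abort("covariate table is missing some genotyped subjects.",
            class = "heritkit_format_error")
    }
    cov_df <- as.data.frame(covariates[cidx,
                                       setdiff(names(covariates),
                                               c("fid", "iid")),
                                       drop = FALSE])
    cov_df[] <- lapply(cov_df, function(v) if (is.character(v)) factor(v) else v)
    x_cov <- cbind(x_cov, model.matrix(~ ., data = cov_df)[, -1, drop = FALSE])
  }
  if (n_pcs > 0) {
    x_cov <- cbind(x_cov, grm_pca(grm_all, k = n_pcs))
  }

  fits <- list()
  rows <- list()
  for (pc in pheno_cols) {
    y <- pheno[[pc]]
    full <- reml_fit(y, x_cov, grms, component_names = names(grms))
    comp_rows <- full$components
    ngen <- length(grms)
    lrt_stat <- p_value <- rep(NA_real_, nrow(comp_rows))
    for (k in seq_len(ngen)) {
      reduced <- if (ngen == 1) {
        reml_null(y, x_cov)
      } else {
        reml_fit(y, x_cov, grms[-k], component_names = names(grms)[-k])
      }
      test <- lrt(full, reduced, df_dropped = 1)
      lrt_stat[k] <- test$statistic
      p_value[k] <- test$p_value
    }
    rows[[pc]] <- mutate(comp_rows,
                         phenotype = pc, loglik = full$loglik,
                         lrt_stat = lrt_stat, p_value = p_value,
                         converged = full$converged)
    fits[[pc]] <- full
  }
  out <- bind_rows(rows)
  out <- out[, c("phenotype", "component", "sigma2", "se", "prop", "prop_se",
                 "loglik", "lrt_stat", "p_value", "converged")]
  attr(out, "fits") <- fits
  class(out) <- c("h2_report", class(out))
  out
}

#' Write heritability results as a GCTA-style TSV
#'
#' One row per component (`component`, `sigma2`, `se`, `prop`, `prop_se`,
#' `loglik`, `lrt_stat`, `p_value`), mirroring the .hsq layout.
#'
#' @param report An `h2_report` from [estimate_h2()].
#' @param path Output TSV path.
#' @export
write_hsq_tsv <- function(report, path) {
  write.table(as.data.frame(report), path, quote = FALSE, row.names = FALSE,
              sep = "\t")
  invisible(path)
}
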