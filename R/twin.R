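#' Twin intraclass correlations
#'
#' Double-entry (pair-symmetrized) Pearson correlation per zygosity group:
#' each pair enters twice, once in each order, which makes the estimate
#' invariant to within-pair labelling.
#'
#' @param twins A `twin_dataset` tibble (`zygosity`, `y1`, `y2`), e.g. from
#'   [simulate_twins()].
#' @return Named list: `r_mz`, `r_dz`, `n_mz`, `n_dz` (pair counts).
#' @examples
#' tw <- simulate_twins(sim_config(n_mz_pairs = 200, n_dz_pairs = 200,
#'                                 seed = 3))
#' twin_correlations(tw)
#' @export
twin_correlations <- function(twins) {
  icc <- function(y1, y2) {
    if (length(y1) < 2) {
      abort("need at least 2 pairs per zygosity group.",
            class = "heritkit_config_error")
    }
    a <- c(y1, y2); b <- c(y2, y1)
    if (sd(a) == 0) {
      abort("zero phenotype variance in a zygosity group.",
            class = "heritkit_degenerate_error")
    }
    cor(a, b)
  }
  mz <- twins[twins$zygosity == "MZ", ]
  dz <- twins[twins$zygosity == "DZ", ]
  list(r_mz = icc(mz$y1, mz$y2), r_dz = icc(dz$y1, dz$y2),
       n_mz = nrow(mz), n_dz = nrow(dz))
}

# Negative bivariate-normal log-likelihood of the twin model with common
# mean mu, common variance v and within-pair covariance cv per group.
twin_neg_loglik <- function(mu, v, cv_mz, cv_dz, stats) {
  group_ll <- function(st, cv) {
    if (st$n == 0) return(0)
    det2 <- v^2 - cv^2
    if (!is.finite(det2) || det2 <= 0 || v <= 0) return(Inf)
    # sum over pairs of the bivariate normal log density
    q <- (v * (st$ss1 + st$ss2) - 2 * cv * st$s12 -
            2 * mu * (v - cv) * (st$sum1 + st$sum2) +
            2 * st$n * mu^2 * (v - cv)) / det2
    0.5 * (st$n * log(det2) + q + 2 * st$n * log(2 * pi))
  }
  group_ll(stats$mz, cv_mz) + group_ll(stats$dz, cv_dz)
}

twin_suff_stats <- function(twins) {
  per_group <- function(df) {
    list(n = nrow(df), sum1 = sum(df$y1), sum2 = sum(df$y2),
         ss1 = sum(df$y1^2), ss2 = sum(df$y2^2), s12 = sum(df$y1 * df$y2))
  }
  list(mz = per_group(twins[twins$zygosity == "MZ", ]),
       dz = per_group(twins[twins$zygosity == "DZ", ]))
}

#' Fit the classical ACE twin model by maximum likelihood
#'
#' Direct numerical ML on the 2x2 covariance structures: MZ pairs share the
#' additive genetic (A) and common environmental (C) variance, DZ pairs half
#' of A and all of C, so `cov_MZ = a2 + c2`, `cov_DZ = a2/2 + c2` with common
#' variance `a2 + c2 + e2` and common mean. Variance components are
#' constrained nonnegative. Nested AE, CE and E submodels are fitted and
#' compared by likelihood ratio.
#'
#' @param twins A `twin_dataset` tibble with both zygosity groups.
#' @return Object of class `ace_fit`: standardized `a2`, `c2`, `e2` (summing
#'   to 1), raw variances, implied `r_mz`/`r_dz`, `minus2ll`, delta-method
#'   `se` per standardized component, `submodels` tibble (model, minus2ll,
#'   lrt_stat vs ACE, df, p), `converged`.
#' @export
fit_ace <- function(twins) {
  if (length(intersect(c("MZ", "DZ"), unique(twins$zygosity))) < 2) {
    abort("fit_ace needs both MZ and DZ pairs.",
          class = "heritkit_config_error")
  }
  stats <- twin_suff_stats(twins)
  y_all <- c(twins$y1, twins$y2)
  mu0 <- mean(y_all); v0 <- var(y_all)

  # moment-based starting values: Falconer estimates from the intraclass
  # correlations, clipped away from the boundary
  f0 <- tryCatch({
    r <- twin_correlations(twins)
    falconer(max(-0.9, min(0.95, r$r_mz)), max(-0.9, min(0.9, r$r_dz)))
  }, error = function(e) c(a2 = 1 / 3, c2 = 1 / 6, e2 = 1 / 2))
  a0 <- min(max(f0[["a2"]], 0.02), 0.95)
  c0 <- min(max(f0[["c2"]], 0.02), 0.9)
  e0 <- max(f0[["e2"]], 0.02)

  fit_sub <- function(free) {
    # free: named logical c(a, c); e always free
    par0 <- c(mu = mu0, log_e = log(v0 * e0),
              if (free["a"]) c(log_a = log(v0 * a0)) else NULL,
              if (free["c"]) c(log_c = log(v0 * c0)) else NULL)
    unpack <- function(par) {
      ex <- function(z) exp(pmin(pmax(z, -40), 40))  # keep optim finite
      a2 <- if (free["a"]) ex(par[["log_a"]]) else 0
      c2 <- if (free["c"]) ex(par[["log_c"]]) else 0
      e2 <- ex(par[["log_e"]])
      list(mu = par[["mu"]], a2 = a2, c2 = c2, e2 = e2)
    }
    obj <- function(par) {
      p <- unpack(par)
      v <- p$a2 + p$c2 + p$e2
      val <- twin_neg_loglik(p$mu, v, p$a2 + p$c2, p$a2 / 2 + p$c2, stats)
      if (!is.finite(val)) 1e10 else val
    }
    opt <- optim(par0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    p <- unpack(opt$par)
    list(par = opt$par, est = p, minus2ll = 2 * opt$value,
         converged = opt$convergence == 0, obj = obj)
  }

  ace <- fit_sub(c(a = TRUE, c = TRUE))
  ae <- fit_sub(c(a = TRUE, c = FALSE))
  ce <- fit_sub(c(a = FALSE, c = TRUE))
  e_only <- fit_sub(c(a = FALSE, c = FALSE))

  est <- ace$est
  total <- est$a2 + est$c2 + est$e2
  std <- c(a2 = est$a2, c2 = est$c2, e2 = est$e2) / total

  # delta-method SEs for the standardized components from the ACE hessian
  se <- rep(NA_real_, 3)
  hess <- tryCatch(optimHess(ace$par, ace$obj), error = function(e) NULL)
  if (!is.null(hess)) {
    cov_par <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(cov_par)) {
      # raw variances are exp of the log-parameters
      raw <- c(a = est$a2, c = est$c2, e = est$e2)
      jac <- matrix(0, 3, length(ace$par),
                    dimnames = list(c("a2", "c2", "e2"), names(ace$par)))
      dvar <- c(log_a = raw[["a"]], log_c = raw[["c"]], log_e = raw[["e"]])
      for (k in 1:3) {
        for (nmpar in intersect(names(ace$par), names(dvar))) {
          which_raw <- match(sub("log_", "", nmpar), c("a", "c", "e"))
          d_raw <- dvar[[nmpar]]
          # d std_k / d raw_j = (I(j==k) * total - raw_k) / total^2
          jac[k, nmpar] <- ((which_raw == k) * total - raw[[k]]) /
            total^2 * d_raw
        }
      }
      vc <- jac %*% cov_par %*% t(jac)
      se <- sqrt(pmax(0, diag(vc)))
    }
  }

  lr <- function(sub, df) {
    stat <- max(0, sub$minus2ll - ace$minus2ll)
    tibble(minus2ll = sub$minus2ll, lrt_stat = stat, df = df,
           p_value = pchisq(stat, df, lower.tail = FALSE))
  }
  submodels <- bind_rows(
    mutate(lr(ae, 1), model = "AE"),
    mutate(lr(ce, 1), model = "CE"),
    mutate(lr(e_only, 2), model = "E")
  )[, c("model", "minus2ll", "lrt_stat", "df", "p_value")]

  structure(list(
    a2 = std[["a2"]], c2 = std[["c2"]], e2 = std[["e2"]],
    se = setNames(se, c("a2", "c2", "e2")),
    variances = c(a2 = est$a2, c2 = est$c2, e2 = est$e2, total = total),
    mean = est$mu,
    r_mz = std[["a2"]] + std[["c2"]],
    r_dz = std[["a2"]] / 2 + std[["c2"]],
    minus2ll = ace$minus2ll,
    submodels = submodels,
    converged = ace$converged,
    n_mz = stats$mz$n, n_dz = stats$dz$n
  ), class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf(
    "<ace_fit> a2 = %.3f, c2 = %.3f, e2 = %.3f (%d MZ / %d DZ pairs)\n",
    x$a2, x$c2, x$e2, x$n_mz, x$n_dz))
  cat(sprintf("  implied rMZ = %.3f, rDZ = %.3f | -2logL = %.2f%s\n",
              x$r_mz, x$r_dz, x$minus2ll,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Falconer moment estimates from twin correlations
#'
#' `a2 = 2 (rMZ - rDZ)`, `c2 = 2 rDZ - rMZ`, `e2 = 1 - rMZ`. Raw moment
#' estimates: no truncation, so values may leave `[0, 1]` in small samples.
#'
#' @param r_mz,r_dz Twin intraclass correlations in `[-1, 1]`.
#' @return Named numeric `(a2, c2, e2)`.
#' @examples
#' falconer(0.62, 0.32)
#' @export
falconer <- function(r_mz, r_dz) {
  stopifnot(abs(r_mz) <= 1, abs(r_dz) <= 1)
  c(a2 = 2 * (r_mz - r_dz), c2 = 2 * r_dz - r_mz, e2 = 1 - r_mz)
}
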