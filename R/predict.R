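#' MCMC settings for the Bayesian samplers
#'
#' Defaults follow common full-scale practice for these models: 30,000
#' iterations with a 5,000-iteration burn-in and thinning of 5, and prior
#' hyperparameters set by the R-squared rule so that the markers (or kernel)
#' are expected a priori to explain `r2_prior` of the phenotypic variance,
#' with 5 prior degrees of freedom on the scaled-inverse-chi-square variance
#' priors. Use smaller settings (e.g. 3,000 / 500 / 2) for desk-scale runs.
#'
#' @param n_iter,burn_in,thin chain length, burn-in and thinning.
#' @param r2_prior prior proportion of variance attributed to the genomic
#'   term.
#' @param df_prior prior degrees of freedom for variance components.
#' @param prob_in,prob_counts prior mean and concentration of the Beta prior
#'   on the BayesB inclusion probability (1 - pi).
#' @param seed integer seed for the chain.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 30000, burn_in = 5000, thin = 5,
                        r2_prior = 0.5, df_prior = 5,
                        prob_in = 0.5, prob_counts = 10, seed = 1L) {
  stopifnot(burn_in < n_iter, thin >= 1, r2_prior > 0, r2_prior < 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), r2_prior = r2_prior,
                 df_prior = df_prior, prob_in = prob_in,
                 prob_counts = prob_counts, seed = as.integer(seed)),
            class = "mcmc_config")
}

new_gp_fit <- function(method, mu, gebv, f = NULL, b = NULL,
                       sigma2_g = NA_real_, sigma2_e = NA_real_,
                       extra = list()) {
  structure(c(list(method = method, mu = mu, gebv = gebv, f = f, b = b,
                   sigma2_g = sigma2_g, sigma2_e = sigma2_e), extra),
            class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("<gp_fit %s: %d GEBVs; sigma2_g = %.4g, sigma2_e = %.4g>\n",
              x$method, length(x$gebv), x$sigma2_g, x$sigma2_e))
  invisible(x)
}

mas_design <- function(M, effect) {
  d <- dosage_of(M)
  switch(effect,
         A = {
           S <- code_additive(d)
           colnames(S) <- paste0(colnames(d), "_A"); S
         },
         D = {
           S <- code_dominance(d)
           colnames(S) <- paste0(colnames(d), "_D"); S
         },
         AD = {
           SA <- code_additive(d); SD <- code_dominance(d)
           colnames(SA) <- paste0(colnames(d), "_A")
           colnames(SD) <- paste0(colnames(d), "_D")
           cbind(SA, SD)
         })
}

drop_aliased <- function(X) {
  q <- qr(X)
  keep <- sort(q$pivot[seq_len(q$rank)])
  if (length(keep) < ncol(X)) {
    warning("dropping ", ncol(X) - length(keep),
            " aliased column(s): ",
            paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)],
                  collapse = ", "))
  }
  X[, keep, drop = FALSE]
}

#' Marker-assisted selection as fixed-effect regression
#'
#' Ordinary least squares of the adjusted phenotype on the coded significant
#' markers: additive (\{-1,0,1\}), dominance (heterozygote indicator) or both
#' stacked. GEBV = M f-hat on the chosen coding. Samples with `NA`
#' phenotype are excluded from the fit but still receive a GEBV.
#'
#' @param y named numeric vector of adjusted phenotypes (NA = to predict),
#'   aligned with the rows of `M`.
#' @param M significant-marker dosages: a [geno] object or samples x markers
#'   matrix.
#' @param effect `"A"`, `"D"` or `"AD"`.
#' @return A `gp_fit` (method `MAS_A`/`MAS_D`/`MAS_AD`).
#' @export
fit_mas <- function(y, M, effect = c("A", "D", "AD")) {
  effect <- match.arg(effect)
  S <- mas_design(M, effect)
  if (ncol(S) == 0) stop("M is empty; MAS needs at least one marker")
  obs <- which(!is.na(y))
  X <- drop_aliased(cbind(`(Intercept)` = 1, S[obs, , drop = FALSE]))
  if (length(obs) <= ncol(X)) stop("more coefficients than phenotyped samples")
  fit <- stats::lm.fit(X, y[obs])
  cf <- fit$coefficients
  f <- stats::setNames(rep(0, ncol(S)), colnames(S))
  got <- intersect(names(cf), names(f))
  f[got] <- cf[got]
  gebv <- drop(S %*% f)
  names(gebv) <- rownames(S)
  s2e <- sum(fit$residuals^2) / max(fit$df.residual, 1)
  new_gp_fit(paste0("MAS_", effect), mu = unname(cf["(Intercept)"]),
             gebv = gebv, f = f, sigma2_e = s2e)
}

# Gibbs sampler for y = X beta + u + e with u ~ N(0, sigma2_g G), flat beta.
# Works in the eigenbasis of G (diagonal full conditionals); missing
# responses are imputed by data augmentation each iteration.
kernel_gibbs <- function(y, G, X, cfg) {
  n <- length(y)
  obs <- which(!is.na(y))
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  pos <- d > 1e-10
  vy <- stats::var(y[obs])
  df0 <- cfg$df_prior
  S0g <- cfg$r2_prior * vy * (df0 + 2) / (df0 * mean(diag(G)))
  S0e <- (1 - cfg$r2_prior) * vy * (df0 + 2) / df0
  set.seed(cfg$seed)

  beta <- rep(0, ncol(X)); beta[1] <- mean(y[obs])
  delta <- rep(0, n)
  s2g <- cfg$r2_prior * vy / mean(diag(G))
  s2e <- (1 - cfg$r2_prior) * vy
  ycomp <- y
  ycomp[-obs] <- mean(y[obs])
  XtXi <- solve(crossprod(X))
  cXtXi <- chol(XtXi)

  keep <- seq(cfg$burn_in + 1L, cfg$n_iter, by = cfg$thin)
  sum_u <- rep(0, n); sum_beta <- rep(0, ncol(X))
  sum_s2g <- 0; sum_s2e <- 0; nkeep <- 0L

  for (it in seq_len(cfg$n_iter)) {
    u <- drop(U %*% delta)
    r <- ycomp - u
    bhat <- drop(XtXi %*% crossprod(X, r))
    beta <- bhat + drop(t(cXtXi) %*% stats::rnorm(ncol(X))) * sqrt(s2e)
    xb <- drop(X %*% beta)
    yt <- drop(crossprod(U, ycomp - xb))
    pv <- 1 / (1 / s2e + 1 / (d[pos] * s2g))
    delta[pos] <- stats::rnorm(sum(pos), pv * yt[pos] / s2e, sqrt(pv))
    delta[!pos] <- 0
    u <- drop(U %*% delta)
    ss_u <- sum(delta[pos]^2 / d[pos])
    s2g <- (ss_u + df0 * S0g) / stats::rchisq(1, df0 + sum(pos))
    res <- ycomp - xb - u
    s2e <- (sum(res^2) + df0 * S0e) / stats::rchisq(1, df0 + n)
    if (!is.finite(s2e) || s2e <= 0) {
      stop("residual variance diverged at iteration ", it)
    }
    if (length(obs) < n) {
      miss <- setdiff(seq_len(n), obs)
      ycomp[miss] <- xb[miss] + u[miss] +
        stats::rnorm(length(miss), 0, sqrt(s2e))
    }
    if (it %in% keep) {
      nkeep <- nkeep + 1L
      sum_u <- sum_u + u; sum_beta <- sum_beta + beta
      sum_s2g <- sum_s2g + s2g; sum_s2e <- sum_s2e + s2e
    }
  }
  list(beta = sum_beta / nkeep, u = sum_u / nkeep,
       sigma2_g = sum_s2g / nkeep, sigma2_e = sum_s2e / nkeep)
}

kernel_fit <- function(y, G, X_all, method, engine, cfg) {
  n <- nrow(G)
  stopifnot(length(y) == n)
  obs <- which(!is.na(y))
  if (engine == "reml") {
    eg <- eigen((G[obs, obs] + t(G[obs, obs])) / 2, symmetric = TRUE)
    if (min(eg$values) < -1e-6 * max(abs(eg$values))) {
      stop("kernel is not positive semidefinite")
    }
    r <- reml_single_kernel(y[obs], X_all[obs, , drop = FALSE], G[obs, obs])
    bl <- kernel_blup(y[obs], X_all[obs, , drop = FALSE], G, obs, r$delta)
    list(beta = bl$beta, u = bl$u, sigma2_g = r$sigma2_g,
         sigma2_e = r$sigma2_e)
  } else {
    kernel_gibbs(y, G, X_all, cfg)
  }
}

#' GBLUP: kernel mixed-model prediction
#'
#' Fits y = mu + h + e with h ~ N(0, sigma2_g G) by REML (eigen-rotated
#' restricted likelihood, the default) or by a Gibbs sampler with
#' missing-response augmentation. Samples with `NA` phenotype are predicted
#' jointly through the kernel. GEBV = h-hat.
#'
#' @param y named numeric vector of adjusted phenotypes (NA = to predict).
#' @param G a `kinship` matrix covering all samples in `y`.
#' @param engine `"reml"` (deterministic, exact) or `"gibbs"`.
#' @param cfg an [mcmc_config()] (used by the Gibbs engine).
#' @return A `gp_fit`.
#' @export
fit_gblup <- function(y, G, engine = c("reml", "gibbs"),
                      cfg = mcmc_config()) {
  engine <- match.arg(engine)
  X <- matrix(1, nrow(G), 1)
  f <- kernel_fit(y, unclass(G), X, "GBLUP", engine, cfg)
  gebv <- stats::setNames(f$u, rownames(G))
  new_gp_fit("GBLUP", mu = f$beta[1], gebv = gebv,
             sigma2_g = f$sigma2_g, sigma2_e = f$sigma2_e)
}

#' RKHS regression on a Gaussian kernel
#'
#' Identical machinery to [fit_gblup()] with the Gaussian kernel from
#' [gaussian_kernel()] in place of the linear relationship matrix.
#'
#' @inheritParams fit_gblup
#' @param K a Gaussian `kinship` matrix.
#' @return A `gp_fit` (method `RKHS`).
#' @export
fit_rkhs <- function(y, K, engine = c("reml", "gibbs"),
                     cfg = mcmc_config()) {
  engine <- match.arg(engine)
  X <- matrix(1, nrow(K), 1)
  f <- kernel_fit(y, unclass(K), X, "RKHS", engine, cfg)
  gebv <- stats::setNames(f$u, rownames(K))
  new_gp_fit("RKHS", mu = f$beta[1], gebv = gebv,
             sigma2_g = f$sigma2_g, sigma2_e = f$sigma2_e)
}

#' MAS-augmented kernel prediction (MAS|GBLUP, MAS|RKHS)
#'
#' Significant markers enter as fixed effects while the remaining genome
#' acts through a kernel built from the non-significant markers only:
#' y = mu + M f + s + e with s ~ N(0, sigma2_s G_W).
#' GEBV = M f-hat + s-hat. With an empty `M` this degenerates to
#' [fit_gblup()] on `G`; with no non-significant markers left (`G = NULL`)
#' it degenerates to [fit_mas()].
#'
#' @inheritParams fit_gblup
#' @param M significant-marker dosages (geno or matrix; may have 0 columns).
#' @param G kernel built from the non-significant markers (trace-normalised
#'   GRM for MAS|GBLUP, Gaussian kernel for MAS|RKHS).
#' @param effect marker coding for `M` (as in [fit_mas()]).
#' @return A `gp_fit` (method `MAS_GBLUP` or `MAS_RKHS` by kernel kind).
#' @export
fit_mas_gp <- function(y, M, G, effect = "A", engine = c("reml", "gibbs"),
                       cfg = mcmc_config()) {
  engine <- match.arg(engine)
  if (is.null(G)) {
    fit <- fit_mas(y, M, effect)
    fit$method <- paste0("MAS_GP_", effect)
    return(fit)
  }
  method <- if (identical(attr(G, "kind"), "gaussian_K")) "MAS_RKHS" else
    "MAS_GBLUP"
  Md <- dosage_of(M)
  if (is.null(Md) || ncol(Md) == 0) {
    fit <- fit_gblup(y, G, engine = engine, cfg = cfg)
    fit$method <- method
    return(fit)
  }
  S <- mas_design(Md, effect)
  X <- drop_aliased(cbind(`(Intercept)` = 1, S))
  f <- kernel_fit(y, unclass(G), X, method, engine, cfg)
  beta <- stats::setNames(f$beta, colnames(X))
  fmark <- beta[-1]
  gebv <- drop(X[, -1, drop = FALSE] %*% fmark) + f$u
  names(gebv) <- rownames(G)
  new_gp_fit(method, mu = unname(beta[1]), gebv = gebv, f = fmark,
             sigma2_g = f$sigma2_g, sigma2_e = f$sigma2_e,
             extra = list(u = f$u))
}

#' BayesB marker-effect model
#'
#' Gibbs sampler in which each marker effect is zero with probability pi and
#' otherwise drawn from a normal slab with its own scaled-inverse-chi-square
#' variance (a scaled-t slab); pi itself carries a Beta prior. Hyperparameters
#' follow the R-squared rule of [mcmc_config()]. GEBV = Z b-hat on the
#' \{-1,0,1\} coding. The chain is seeded and reproducible.
#'
#' @param y named numeric vector of adjusted phenotypes (NA = to predict).
#' @param Z full marker panel ([geno] or dosage matrix).
#' @param cfg an [mcmc_config()].
#' @param pi_fixed optional fixed value for the exclusion probability pi
#'   (disables the Beta update; `pi_fixed = 0` gives a Bayesian
#'   ridge-with-marker-variances model).
#' @return A `gp_fit` (method `BayesB`) with posterior-mean effects `b` and
#'   posterior inclusion probabilities in `$prob_in`.
#' @export
fit_bayesb <- function(y, Z, cfg = mcmc_config(), pi_fixed = NULL) {
  Zc <- code_additive(Z)
  obs <- which(!is.na(y))
  yo <- y[obs]
  Zo <- Zc[obs, , drop = FALSE]
  vy <- stats::var(yo)
  df0 <- cfg$df_prior
  msx <- sum(apply(Zo, 2, stats::var))
  prob_in <- cfg$prob_in
  Sb <- cfg$r2_prior * vy * (df0 + 2) / (df0 * prob_in * msx)
  Se <- (1 - cfg$r2_prior) * vy * (df0 + 2) / df0
  set.seed(cfg$seed)
  res <- bayesb_gibbs(yo, Zo, cfg$n_iter, cfg$burn_in, cfg$thin,
                      df0, Sb, df0, Se,
                      (1 - prob_in) * cfg$prob_counts,  # Beta prior on pi
                      prob_in * cfg$prob_counts,        # (exclusion prob.)

                      if (is.null(pi_fixed)) -1 else pi_fixed)
  b <- stats::setNames(drop(res$b), colnames(Zc))
  gebv <- drop(Zc %*% b)
  names(gebv) <- rownames(Zc)
  new_gp_fit("BayesB", mu = res$mu, gebv = gebv, b = b,
             sigma2_g = stats::var(gebv[obs]), sigma2_e = res$sigma2_e,
             extra = list(prob_in = drop(res$d), pi_excl = res$pi))
}

#' Training-testing cross-validation of predictive ability
#'
#' Repeatedly splits the phenotyped samples into a random training fraction
#' and a test remainder, fits the supplied model on the training set (test
#' phenotypes masked to `NA`), and records the Pearson correlation between
#' the test phenotypes and their GEBVs. Replicate k uses seed `seed + k`, so
#' individual replicates can be re-run. The summary reports the mean
#' predictive ability, its standard deviation and a one-sample t-test
#' against zero.
#'
#' @param y named numeric vector of adjusted phenotypes.
#' @param fitter function `function(y_masked) -> gp_fit` returning GEBVs for
#'   all samples.
#' @param n_reps number of random splits.
#' @param train_frac fraction of samples in the training set.
#' @param seed master seed for the splits.
#' @param method label stored on the result.
#' @return A `cv_result`: per-replicate correlations plus summary
#'   statistics.
#' @export
cross_validate <- function(y, fitter, n_reps = 50, train_frac = 0.75,
                           seed = 1L, method = "model") {
  n <- length(y)
  if (n < 20) stop("need at least 20 phenotyped samples")
  rs <- vapply(seq_len(n_reps), function(k) {
    set.seed(seed + k)
    test <- sample.int(n, round(n * (1 - train_frac)))
    ymask <- y
    ymask[test] <- NA
    fit <- fitter(ymask)
    gt <- fit$gebv[test]
    if (stats::sd(gt) == 0 || stats::sd(y[test]) == 0) {
      warning("constant GEBVs in replicate ", k, "; recorded as NA")
      return(NA_real_)
    }
    stats::cor(y[test], gt)
  }, numeric(1))
  ok <- rs[is.finite(rs)]
  tt <- if (length(ok) > 1 && stats::sd(ok) > 0) {
    tryCatch(stats::t.test(ok, mu = 0)$p.value,
             error = function(e) NA_real_)
  } else NA_real_
  structure(list(method = method,
                 reps = tibble::tibble(rep = seq_len(n_reps), r = rs),
                 mean_pa = mean(ok), sd_pa = stats::sd(ok),
                 p_value = tt, n_reps = n_reps),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s: mean PA %.3f (sd %.3f, %d reps, t-test p %.3g)>\n",
              x$method, x$mean_pa, x$sd_pa, x$n_reps, x$p_value))
  invisible(x)
}

#' Cross-validate a named prediction method on a hybrid panel
#'
#' Convenience wrapper that builds the required kernels once (trace-
#' normalised GRM on all markers, the non-significant-marker GRM, and their
#' Gaussian kernels) and runs [cross_validate()] for one of the eight
#' supported methods.
#'
#' @param y named numeric vector of adjusted phenotypes aligned with
#'   `hybrids`.
#' @param method one of `"mas_a"`, `"mas_d"`, `"mas_ad"`, `"bayesb"`,
#'   `"gblup"`, `"rkhs"`, `"mas_gblup"`, `"mas_rkhs"`.
#' @param hybrids a [geno] object of hybrid genotypes.
#' @param sig_markers character vector of significant marker ids (matrix M);
#'   the complement forms matrix W.
#' @param cfg an [mcmc_config()] for the samplers.
#' @param engine engine for the kernel models (`"reml"` or `"gibbs"`).
#' @param h Gaussian-kernel bandwidth.
#' @param n_reps,train_frac,seed see [cross_validate()].
#' @return A `cv_result`.
#' @export
gp_cross_validate <- function(y, method, hybrids, sig_markers = character(),
                              cfg = mcmc_config(), engine = "reml", h = 1,
                              n_reps = 50, train_frac = 0.75, seed = 1L) {
  method <- match.arg(tolower(method),
                      c("mas_a", "mas_d", "mas_ad", "bayesb", "gblup",
                        "rkhs", "mas_gblup", "mas_rkhs"))
  dos <- hybrids$dosage
  sig <- intersect(sig_markers, colnames(dos))
  Mmat <- dos[, sig, drop = FALSE]
  Wids <- setdiff(colnames(dos), sig)
  fitter <- switch(
    method,
    mas_a = function(ym) fit_mas(ym, Mmat, "A"),
    mas_d = function(ym) fit_mas(ym, Mmat, "D"),
    mas_ad = function(ym) fit_mas(ym, Mmat, "AD"),
    bayesb = function(ym) fit_bayesb(ym, dos, cfg),
    gblup = {
      G <- grm_trace_norm(dos)
      function(ym) fit_gblup(ym, G, engine = engine, cfg = cfg)
    },
    rkhs = {
      K <- gaussian_kernel(grm_trace_norm(dos), h = h)
      function(ym) fit_rkhs(ym, K, engine = engine, cfg = cfg)
    },
    mas_gblup = {
      GW <- if (length(Wids)) grm_trace_norm(dos, markers = Wids) else NULL
      function(ym) fit_mas_gp(ym, Mmat, GW, engine = engine, cfg = cfg)
    },
    mas_rkhs = {
      KW <- if (length(Wids)) {
        gaussian_kernel(grm_trace_norm(dos, markers = Wids), h = h)
      } else NULL
      function(ym) fit_mas_gp(ym, Mmat, KW, engine = engine, cfg = cfg)
    })
  cross_validate(y, fitter, n_reps = n_reps, train_frac = train_frac,
                 seed = seed, method = toupper(method))
}
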