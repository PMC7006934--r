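#' GWAS configuration
#'
#' @param coding marker coding tested: `"A"` (additive, \{-1,0,1\}), `"D"`
#'   (dominance, heterozygote indicator) or `"AD"` (both, each tested by a
#'   marginal 1-df Wald test).
#' @param kinship polygenic control: `"A"`, `"D"`, `"AD"` (both kernels) or
#'   `"none"`.
#' @param n_pc number of principal-component covariates (0-3).
#' @param n_perm permutation replicates for the significance threshold.
#' @param alpha family-wise error rate for the threshold.
#' @param seed integer seed for the permutations.
#' @return A list of class `gwas_config`.
#' @export
gwas_config <- function(coding = c("A", "D", "AD"),
                        kinship = c("A", "D", "AD", "none"),
                        n_pc = 0, n_perm = 400, alpha = 0.05, seed = 1L) {
  coding <- match.arg(coding)
  kinship <- match.arg(kinship)
  stopifnot(n_pc %in% 0:3, n_perm >= 20, alpha > 0, alpha < 1)
  structure(list(coding = coding, kinship = kinship, n_pc = as.integer(n_pc),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed)),
            class = "gwas_config")
}

#' Null-model variance components and whitening transform
#'
#' Fits the marker-free mixed model y = X beta + v [+ o] + e with v and o
#' polygenic effects on the additive and/or dominance kinships, by REML.
#' The fitted covariance is spectrally decomposed once and cached as a
#' whitening matrix, so each subsequent single-marker test is a rotated
#' ordinary regression (the P3D convention: population parameters are
#' determined once, not re-estimated per marker).
#'
#' @param y named numeric phenotype vector.
#' @param g a [geno] object for the same samples (used for PCs and
#'   kinships).
#' @param config a [gwas_config()].
#' @return A list of class `gwas_null` with the whitening matrix, fixed
#'   design and variance components.
#' @export
gwas_null <- function(y, g, config = gwas_config()) {
  n <- length(y)
  covar <- pca_covariates(g, config$n_pc)
  X <- cbind(`(Intercept)` = rep(1, n), covar)
  kin <- list()
  if (config$kinship %in% c("A", "AD")) kin$A <- unclass(grm_additive(g))
  if (config$kinship %in% c("D", "AD")) kin$D <- unclass(grm_dominance(g))
  if (length(kin) == 2 &&
      max(abs(kin$A - kin$D)) < 1e-10) {
    warning("additive and dominance kinships are identical; ",
            "only their sum is identified")
  }
  if (length(kin) == 0) {
    Wt <- diag(n)
    vc <- tibble::tibble(component = "residual", variance = stats::var(y))
  } else if (length(kin) == 1) {
    r <- reml_single_kernel(y, X, kin[[1]])
    eg <- eigen((kin[[1]] + t(kin[[1]])) / 2, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    Wt <- t(eg$vectors) / sqrt(d + r$delta)
    vc <- tibble::tibble(
      component = c(paste0("sigma2_", tolower(names(kin))), "residual"),
      variance = c(r$sigma2_g, r$sigma2_e))
  } else {
    r <- reml_multi_kernel(y, X, kin)
    if (!r$converged) stop("null-model REML did not converge")
    Sig <- diag(n) + r$theta[1] * kin[[1]] + r$theta[2] * kin[[2]]
    eg <- eigen((Sig + t(Sig)) / 2, symmetric = TRUE)
    Wt <- t(eg$vectors) / sqrt(pmax(eg$values, 1e-12))
    vc <- tibble::tibble(
      component = c("sigma2_a", "sigma2_d", "residual"),
      variance = c(r$sigma2_k, r$sigma2_e))
  }
  structure(list(Wt = Wt, X = X, varcomp = vc, config = config, n = n),
            class = "gwas_null")
}

# p-values and effects for whitened phenotypes Yw (n x B) against the
# whitened, X-residualised marker codings; fully vectorised over markers and
# phenotype columns.
scan_core <- function(Yw, Qx, SA = NULL, SD = NULL) {
  n <- nrow(Yw)
  q <- ncol(Qx)
  rs <- function(M) M - Qx %*% crossprod(Qx, M)
  Yr <- rs(Yw)
  yy <- colSums(Yr^2)
  out <- list()
  tol <- 1e-10
  if (!is.null(SA) && is.null(SD)) {
    Sr <- rs(SA)
    ss <- colSums(Sr^2)
    df <- n - q - 1
    SY <- crossprod(Sr, Yr)
    beta <- SY / ifelse(ss > tol, ss, NA)
    RSS <- pmax(outer(rep(1, nrow(SY)), yy) - SY * beta, 0)
    se <- sqrt(RSS / df / ss)
    tt <- beta / se
    p <- 2 * stats::pt(-abs(tt), df)
    out$A <- list(beta = beta, se = se, p = p)
  } else if (is.null(SA) && !is.null(SD)) {
    res <- scan_core(Yw, Qx, SA = SD)
    out$D <- res$A
  } else {
    S1 <- rs(SA); S2 <- rs(SD)
    a11 <- colSums(S1^2); a22 <- colSums(S2^2); a12 <- colSums(S1 * S2)
    det <- a11 * a22 - a12^2
    df <- n - q - 2
    B1 <- crossprod(S1, Yr); B2 <- crossprod(S2, Yr)
    scale_det <- pmax(a11, tol) * pmax(a22, tol)
    ok2 <- det > tol * scale_det & a11 > tol & a22 > tol
    detN <- ifelse(ok2, det, NA)
    beta1 <- (a22 * B1 - a12 * B2) / detN
    beta2 <- (a11 * B2 - a12 * B1) / detN
    RSS <- pmax(outer(rep(1, nrow(B1)), yy) - beta1 * B1 - beta2 * B2, 0)
    s2 <- RSS / df
    se1 <- sqrt(s2 * a22 / detN); se2 <- sqrt(s2 * a11 / detN)
    p1 <- 2 * stats::pt(-abs(beta1 / se1), df)
    p2 <- 2 * stats::pt(-abs(beta2 / se2), df)
    # degenerate markers: no dominance (or no additive) variation left
    onlyA <- !ok2 & a11 > tol
    onlyD <- !ok2 & a11 <= tol & a22 > tol
    if (any(!ok2)) {
      resA <- scan_core(Yw, Qx, SA = SA)$A
      beta1[!ok2, ] <- NA; se1[!ok2, ] <- NA; p1[!ok2, ] <- NA
      beta2[!ok2, ] <- NA; se2[!ok2, ] <- NA; p2[!ok2, ] <- NA
      beta1[onlyA, ] <- resA$beta[onlyA, ]
      se1[onlyA, ] <- resA$se[onlyA, ]
      p1[onlyA, ] <- resA$p[onlyA, ]
      if (any(onlyD)) {
        resD <- scan_core(Yw, Qx, SA = SD)$A
        beta2[onlyD, ] <- resD$beta[onlyD, ]
        se2[onlyD, ] <- resD$se[onlyD, ]
        p2[onlyD, ] <- resD$p[onlyD, ]
      }
    }
    out$A <- list(beta = beta1, se = se1, p = p1)
    out$D <- list(beta = beta2, se = se2, p = p2)
  }
  out
}

scan_matrices <- function(g, coding, Wt) {
  d <- dosage_of(g)
  SA <- if (coding %in% c("A", "AD")) Wt %*% code_additive(d) else NULL
  SD <- if (coding %in% c("D", "AD")) Wt %*% code_dominance(d) else NULL
  list(SA = SA, SD = SD)
}

#' Single-marker mixed-model association scan
#'
#' Tests every marker for association with the adjusted phenotype by
#' generalised least squares under the null-calibrated covariance
#' (see [gwas_null()]): for each marker, the model
#' y = mu + PCs + S m + polygenic + e is fitted with the marker coded
#' additively, by dominance, or both; each effect gets a marginal 1-df Wald
#' test. Markers whose coding has no variation (monomorphic, or no
#' heterozygotes under D) are reported with `NA` p-values.
#'
#' @inheritParams gwas_null
#' @param null an optional pre-computed [gwas_null()] cache (recomputed when
#'   `NULL`).
#' @return An object of class `gwas_scan`: a tibble (`marker_id`, `chrom`,
#'   `pos`, `maf`, `effect`, `beta`, `se`, `p`) with the genomic inflation
#'   factor lambda, the config and the null cache as attributes.
#' @export
gwas_scan <- function(y, g, config = gwas_config(), null = NULL) {
  if (is.null(null)) null <- gwas_null(y, g, config)
  Wt <- null$Wt
  Yw <- Wt %*% matrix(y, ncol = 1)
  Xw <- Wt %*% null$X
  Qx <- qr.Q(qr(Xw))
  sm <- scan_matrices(g, config$coding, Wt)
  res <- scan_core(Yw, Qx, SA = sm$SA, SD = sm$SD)
  st <- marker_stats(g)
  rows <- purrr::map_dfr(names(res), function(eff) {
    tibble::tibble(marker_id = st$marker_id, chrom = st$chrom, pos = st$pos,
                   maf = st$maf, effect = eff,
                   beta = unname(drop(res[[eff]]$beta)),
                   se = unname(drop(res[[eff]]$se)),
                   p = unname(drop(res[[eff]]$p)))
  })
  pv <- rows$p[is.finite(rows$p)]
  lambda <- stats::median(stats::qchisq(1 - pv, df = 1)) /
    stats::qchisq(0.5, df = 1)
  structure(rows, class = c("gwas_scan", class(rows)),
            lambda = lambda, config = config, null = null)
}

#' Permutation-based family-wise significance threshold
#'
#' Permutes the phenotype vector (covariates and kinship rows are left in
#' place), repeats the whole scan for each permutation, records the minimum
#' p-value, and returns the empirical alpha-quantile of the minimum-p
#' distribution -- the order statistic `ceiling(alpha * n_perm)` (the 20th
#' smallest of 400 at alpha = 0.05). A scan p-value at or below this
#' threshold is family-wise significant at level alpha.
#'
#' @inheritParams gwas_scan
#' @return The threshold on the p-value scale, with the minimum-p
#'   distribution in `attr(, "min_p")`.
#' @export
permutation_threshold <- function(y, g, config = gwas_config(),
                                  null = NULL) {
  if (config$n_perm < 1 / config$alpha) {
    stop("n_perm must be at least 1/alpha for the quantile to exist")
  }
  if (is.null(null)) null <- gwas_null(y, g, config)
  n <- length(y)
  set.seed(config$seed)
  Yp <- vapply(seq_len(config$n_perm), function(b) y[sample.int(n)],
               numeric(n))
  Yw <- null$Wt %*% Yp
  Xw <- null$Wt %*% null$X
  Qx <- qr.Q(qr(Xw))
  sm <- scan_matrices(g, config$coding, null$Wt)
  res <- scan_core(Yw, Qx, SA = sm$SA, SD = sm$SD)
  pmat <- do.call(rbind, lapply(res, function(r) r$p))
  min_p <- apply(pmat, 2, min, na.rm = TRUE)
  thr <- sort(min_p)[ceiling(config$alpha * config$n_perm)]
  attr(thr, "min_p") <- min_p
  thr
}

#' Markers significant against a permutation threshold
#'
#' @param scan a [gwas_scan()] result.
#' @param threshold p-value threshold (from [permutation_threshold()]).
#' @return The significant subset of the scan tibble.
#' @export
significant_markers <- function(scan, threshold) {
  dplyr::filter(tibble::as_tibble(scan), is.finite(.data$p),
                .data$p <= threshold)
}

#' Pick the best-calibrated scan by genomic inflation
#'
#' Computes the genomic inflation factor lambda (median observed chi-square
#' over its null median, 0.4549) for each candidate scan and returns the one
#' with lambda closest to 1; ties are broken toward fewer principal
#' components.
#'
#' @param scans a list of [gwas_scan()] results.
#' @return The selected scan; the comparison table is in
#'   `attr(, "comparison")`.
#' @export
select_model <- function(scans) {
  stopifnot(length(scans) >= 1)
  cmp <- purrr::map_dfr(seq_along(scans), function(i) {
    s <- scans[[i]]
    cf <- attr(s, "config")
    tibble::tibble(idx = i, coding = cf$coding, kinship = cf$kinship,
                   n_pc = cf$n_pc, lambda = attr(s, "lambda"))
  }) |>
    dplyr::arrange(abs(.data$lambda - 1), .data$n_pc)
  best <- scans[[cmp$idx[1]]]
  attr(best, "comparison") <- cmp
  best
}

#' Allele substitution effect
#'
#' alpha = a + d (q - p), with q = 1 - p: the average effect of swapping one
#' allele, combining the additive effect and the frequency-weighted
#' dominance deviation.
#'
#' @param a additive effect; `d` dominance deviation; `p` frequency of the
#'   allele coded +1.
#' @param d dominance deviation.
#' @param p allele frequency in (0, 1).
#' @return Numeric vector of substitution effects.
#' @export
ase <- function(a, d, p) {
  stopifnot(all(p > 0 & p < 1))
  a + d * ((1 - p) - p)
}

#' Per-marker heritability decomposition
#'
#' For an additive scan, H2 = 2 p q alpha^2 / Var(g-hat) with alpha the
#' regression coefficient. For an additive + dominance scan, the additive
#' component is H2 = 2 p q [a + d (q - p)]^2 / Var(g-hat) and the dominance
#' component is H2 = 4 p^2 q^2 d^2 / Var(g-hat).
#'
#' @param p allele frequency (or MAF) in (0, 1); vectorised.
#' @param var_g variance of the adjusted phenotype.
#' @param beta regression coefficient (additive mode).
#' @param a,d additive effect and dominance deviation (AD mode).
#' @param mode `"additive"` or `"AD"`.
#' @return A tibble (`p`, `mode`, `effect`, `alpha`, `a`, `d`, `h2`); AD
#'   mode returns an additive and a dominance row per marker.
#' @export
marker_h2 <- function(p, var_g, beta = NULL, a = NULL, d = NULL,
                      mode = c("additive", "AD")) {
  mode <- match.arg(mode)
  if (any(var_g <= 0)) stop("var_g must be > 0")
  stopifnot(all(p > 0 & p < 1))
  q <- 1 - p
  if (mode == "additive") {
    stopifnot(!is.null(beta))
    tibble::tibble(p = p, mode = mode, effect = "A", alpha = beta,
                   a = NA_real_, d = NA_real_,
                   h2 = 2 * p * q * beta^2 / var_g)
  } else {
    stopifnot(!is.null(a), !is.null(d))
    al <- ase(a, d, p)
    dplyr::bind_rows(
      tibble::tibble(p = p, mode = mode, effect = "A", alpha = al,
                     a = a, d = d, h2 = 2 * p * q * al^2 / var_g),
      tibble::tibble(p = p, mode = mode, effect = "D", alpha = al,
                     a = a, d = d, h2 = 4 * p^2 * q^2 * d^2 / var_g)
    )
  }
}
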