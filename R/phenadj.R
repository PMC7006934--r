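check_plot_table <- function(plots) {
  need <- c("entry_id", "is_check", "site", "year", "n_regime", "block_id",
            "yield")
  miss <- setdiff(need, names(plots))
  if (length(miss)) stop("plot table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(plots$n_regime %in% c("LN", "IN"))) {
    stop("n_regime must be 'LN' or 'IN'")
  }
  invisible(plots)
}

phen_factors <- function(pl) {
  pl$entry <- factor(pl$entry_id)
  pl$env <- factor(paste(pl$site, pl$year, sep = "_"))
  pl$chk_env <- factor(ifelse(pl$is_check,
                              paste(pl$entry_id, pl$site, pl$year, sep = "_"),
                              "none"))
  pl$chk_env <- stats::relevel(pl$chk_env, ref = "none")
  pl$hyb_ind <- as.numeric(!pl$is_check)
  pl$chk_ind <- as.numeric(pl$is_check)
  pl$block <- factor(pl$block_id)
  pl
}

#' Adjusted entry means for one nitrogen regime
#'
#' Fits the augmented-design mixed model with check, hybrid, environment
#' (site x year) and check-by-environment as fixed effects and
#' block-within-environment as random, by REML. Because the test entries are
#' unreplicated, the residual and block variances are identified by the
#' replicated checks. The adjusted mean of a hybrid is its fixed-effect
#' estimate evaluated at the average environment.
#'
#' @param plots a plot-record tibble (`entry_id`, `is_check`, `site`,
#'   `year`, `n_regime`, `block_id`, `yield`).
#' @param regime `"LN"` or `"IN"`; the subset of plots to use.
#' @return A list with `means` (tibble `entry_id`, `adj_mean` for hybrids),
#'   `varcomp` (tibble `sigma2_b`, `sigma2_e`) and the lme4 `fit`.
#' @export
fit_adjusted_means <- function(plots, regime = c("LN", "IN")) {
  regime <- match.arg(regime)
  check_plot_table(plots)
  pl <- phen_factors(dplyr::filter(plots, .data$n_regime == regime))
  if (dplyr::n_distinct(pl$env) < 2) stop("need at least 2 environments")
  if (!any(pl$is_check)) stop("no replicated checks in the plot table")
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(yield ~ 0 + entry + env + chk_env + (1 | block),
               data = pl, REML = TRUE,
               control = lme4::lmerControl(check.rankX = "silent.drop.cols",
                                           calc.derivs = FALSE))
  ))
  b <- lme4::fixef(fit)
  env_levels <- levels(pl$env)
  env_coefs <- stats::setNames(rep(0, length(env_levels)),
                               paste0("env", env_levels))
  found <- intersect(names(env_coefs), names(b))
  env_coefs[found] <- b[found]
  env_mean <- mean(env_coefs)         # reference env contributes 0
  hyb <- sort(unique(pl$entry_id[!pl$is_check]))
  entry_coef <- b[paste0("entry", hyb)]
  means <- tibble::tibble(entry_id = hyb,
                          adj_mean = unname(entry_coef) + env_mean)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2b <- vc$vcov[vc$grp == "block"][1]
  s2e <- vc$vcov[vc$grp == "Residual"][1]
  list(means = means,
       varcomp = tibble::tibble(sigma2_b = s2b, sigma2_e = s2e),
       fit = fit)
}

#' Plot- and entry-mean-level heritability
#'
#' Refits the model of [fit_adjusted_means()] with hybrid, environment and
#' check-by-environment as random effects, then evaluates
#' plot-level H2 = s2_g / (s2_g + s2_ga + s2_e) and entry-mean-level
#' H2 = s2_g / (s2_g + s2_ga / a + s2_e / (a r)) at the REML estimates,
#' where a is the number of environments and r the number of replications.
#'
#' @inheritParams fit_adjusted_means
#' @param n_env number of environments `a`; inferred from the data when
#'   `NULL`.
#' @param n_rep number of replications `r` per environment (1 for
#'   unreplicated augmented trials).
#' @return A list with `h2_plot`, `h2_entry` and the `varcomp` tibble
#'   (`sigma2_g`, `sigma2_ga`, `sigma2_b`, `sigma2_e`).
#' @export
heritability <- function(plots, regime = c("LN", "IN"), n_env = NULL,
                         n_rep = 1) {
  regime <- match.arg(regime)
  check_plot_table(plots)
  pl <- phen_factors(dplyr::filter(plots, .data$n_regime == regime))
  if (is.null(n_env)) n_env <- dplyr::n_distinct(pl$env)
  pl$check_f <- factor(ifelse(pl$is_check, pl$entry_id, "TEST"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(yield ~ 0 + check_f + (0 + hyb_ind | entry) + (1 | env) +
                 (0 + chk_ind | chk_env) + (1 | block),
               data = pl, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE))
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(grp) {
    v <- vc$vcov[vc$grp == grp][1]
    if (is.na(v)) 0 else max(v, 0)
  }
  s2g <- pick("entry"); s2ga <- pick("chk_env"); s2b <- pick("block")
  s2e <- vc$vcov[vc$grp == "Residual"][1]
  h <- heritability_from_varcomp(s2g, s2ga, s2e, a = n_env, r = n_rep)
  list(h2_plot = h$h2_plot, h2_entry = h$h2_entry,
       varcomp = tibble::tibble(sigma2_g = s2g, sigma2_ga = s2ga,
                                sigma2_b = s2b, sigma2_e = s2e),
       fit = fit)
}

#' Heritability formulas from variance components
#'
#' @param sigma2_g,sigma2_ga,sigma2_e genotypic (hybrids),
#'   check-by-environment and residual variances (negative inputs are
#'   clamped to 0 with a warning).
#' @param a number of environments; `r` replications per environment.
#' @param r number of replications.
#' @return A list with `h2_plot` and `h2_entry`.
#' @export
heritability_from_varcomp <- function(sigma2_g, sigma2_ga, sigma2_e,
                                      a = 4, r = 1) {
  v <- c(sigma2_g, sigma2_ga, sigma2_e)
  if (any(v < 0)) {
    warning("negative variance component(s) clamped to 0")
    sigma2_g <- max(sigma2_g, 0); sigma2_ga <- max(sigma2_ga, 0)
    sigma2_e <- max(sigma2_e, 0)
  }
  list(
    h2_plot = sigma2_g / (sigma2_g + sigma2_ga + sigma2_e),
    h2_entry = sigma2_g / (sigma2_g + sigma2_ga / a + sigma2_e / (a * r))
  )
}

#' Low-nitrogen tolerance index
#'
#' LNTI_i = (1 - GY_LN_i / GY_IN_i) x 100, in percent. Negative values mean
#' the entry yielded more under low nitrogen (tolerance gain).
#'
#' @param gy_ln,gy_in adjusted grain yields (Mg/ha) under low and ideal
#'   nitrogen.
#' @return Numeric vector of LNTI values (`NA` where `gy_in <= 0`).
#' @export
lnti <- function(gy_ln, gy_in) {
  out <- (1 - gy_ln / gy_in) * 100
  out[gy_in <= 0] <- NA_real_
  out
}

#' Adjusted means under both regimes plus LNTI
#'
#' Runs [fit_adjusted_means()] for LN and IN, joins the per-hybrid adjusted
#' yields and computes the LNTI. Entries with non-positive ideal-N yield are
#' flagged and excluded; optional absolute LNTI bounds flag further entries
#' (no bound by default).
#'
#' @inheritParams fit_adjusted_means
#' @param lnti_bounds optional length-2 numeric `c(lo, hi)`; entries with
#'   LNTI outside the bounds are flagged `excluded`.
#' @return A tibble (`entry_id`, `gy_ln`, `gy_in`, `lnti`, `excluded`).
#' @export
adjusted_means <- function(plots, lnti_bounds = NULL) {
  ln <- fit_adjusted_means(plots, "LN")$means
  inn <- fit_adjusted_means(plots, "IN")$means
  out <- dplyr::inner_join(
    dplyr::rename(ln, gy_ln = "adj_mean"),
    dplyr::rename(inn, gy_in = "adj_mean"),
    by = "entry_id"
  ) |>
    dplyr::mutate(lnti = lnti(.data$gy_ln, .data$gy_in),
                  excluded = is.na(.data$lnti))
  if (!is.null(lnti_bounds)) {
    stopifnot(length(lnti_bounds) == 2)
    out$excluded <- out$excluded | out$lnti < lnti_bounds[1] |
      out$lnti > lnti_bounds[2]
  }
  out
}

#' Screen trial factors for significance
#'
#' Reporting helper for the joint model across regimes: Wald F tests of the
#' fixed site, year and nitrogen-regime terms and a likelihood-ratio test of
#' the block-within-environment random term. Nothing downstream is gated on
#' these p-values; the per-regime analysis is always run.
#'
#' @inheritParams fit_adjusted_means
#' @return A tibble (`term`, `test`, `statistic`, `p_value`).
#' @export
screen_factors <- function(plots) {
  check_plot_table(plots)
  pl <- phen_factors(plots)
  full <- suppressMessages(
    lme4::lmer(yield ~ site + year + n_regime + (1 | block), data = pl,
               REML = FALSE))
  noblk <- stats::lm(yield ~ site + year + n_regime, data = pl)
  lrt_stat <- max(0, 2 * (stats::logLik(full) - stats::logLik(noblk)))
  lrt_p <- stats::pchisq(lrt_stat, df = 1, lower.tail = FALSE) / 2
  wald <- as.data.frame(stats::anova(full))
  tibble::tibble(
    term = c(rownames(wald), "block"),
    test = c(rep("Wald F", nrow(wald)), "LRT"),
    statistic = c(wald$`F value`, lrt_stat),
    p_value = c(stats::pf(wald$`F value`, wald$npar,
                          nrow(pl) - sum(wald$npar) - 1,
                          lower.tail = FALSE), lrt_p)
  )
}
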