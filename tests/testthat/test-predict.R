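test_that("MAS recovers planted fixed effects and hand OLS", {
  g <- random_geno(40, 3, seed = 20)
  z1 <- code_additive(g$dosage)[, 1]
  y <- stats::setNames(5 + 2 * z1, rownames(g$dosage))
  fit <- fit_mas(y, g, "A")
  expect_equal(unname(fit$f["M1_A"]), 2, tolerance = 1e-10)
  expect_equal(unname(fit$f[c("M2_A", "M3_A")]), c(0, 0), tolerance = 1e-10)
  expect_lt(fit$sigma2_e, 1e-16)

  # 4-sample 1-marker toy against hand OLS
  gm <- tiny_geno(matrix(c(0, 1, 1, 2), 4, 1))
  y4 <- stats::setNames(c(1.0, 2.0, 2.5, 3.6), rownames(gm$dosage))
  z <- c(-1, 0, 0, 1)
  slope <- sum((z - mean(z)) * (y4 - mean(y4))) / sum((z - mean(z))^2)
  f4 <- fit_mas(y4, gm, "A")
  expect_equal(unname(f4$f[1]), slope, tolerance = 1e-12)

  # constant column is aliased with the intercept and dropped
  gc <- tiny_geno(cbind(rep(2, 10), rbinom(10, 2, 0.5)))
  yc <- stats::setNames(rnorm(10), rownames(gc$dosage))
  expect_warning(fc <- fit_mas(yc, gc, "A"), "aliased")
  expect_equal(unname(fc$f["M1_A"]), 0)
})

test_that("GBLUP equals the ridge-regression oracle on a matched kernel", {
  set.seed(21)
  g <- random_geno(20, 50, seed = 21)
  Z <- g$dosage - 1
  y <- stats::setNames(drop(Z %*% rnorm(50, 0, 0.3)) + rnorm(20),
                       rownames(g$dosage))
  G <- grm_trace_norm(g)
  ymask <- y
  ymask[16:20] <- NA
  fit <- fit_gblup(ymask, G)
  obs <- 1:15
  cc <- sum(diag(tcrossprod(Z))) / 20     # G = ZZ'/cc
  delta <- fit$sigma2_e / fit$sigma2_g
  Zo <- Z[obs, , drop = FALSE]
  ridge <- drop(Z %*% crossprod(Zo, solve(tcrossprod(Zo) + cc * delta *
                                            diag(15),
                                          y[obs] - fit$mu)))
  expect_lt(max(abs(fit$gebv - ridge)), 1e-6)
})

test_that("GBLUP with identity kernel shrinks deviations by the heritability ratio", {
  set.seed(22)
  y <- stats::setNames(rnorm(60, 10, 2), paste0("S", 1:60))
  G <- diag(60)
  dimnames(G) <- list(names(y), names(y))
  fit <- fit_gblup(y, structure(G, kind = "trace_norm",
                                class = c("kinship", "matrix")))
  shrink <- fit$sigma2_g / (fit$sigma2_g + fit$sigma2_e)
  expect_equal(unname(fit$gebv), shrink * (y - fit$mu),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("RKHS with the linear kernel reproduces GBLUP", {
  g <- random_geno(25, 60, seed = 23)
  set.seed(23)
  y <- stats::setNames(rnorm(25), rownames(g$dosage))
  G <- grm_trace_norm(g)
  expect_equal(fit_rkhs(y, G)$gebv, fit_gblup(y, G)$gebv, tolerance = 1e-8)
})

test_that("Gibbs and REML engines agree on GEBV rankings", {
  pan <- small_panel(seed = 24, n1 = 10, n2 = 8, m = 300, n_hyb = 80)
  sim <- simulate_phenotypes(pan$hybrids, pan$design, pan$cfg)
  y <- entry_phenotype(sim$truth, h2 = 0.6, seed = 24, what = "g_in")
  G <- grm_trace_norm(pan$hybrids)
  fr <- fit_gblup(y, G, engine = "reml")
  fg <- fit_gblup(y, G, engine = "gibbs",
                  cfg = mcmc_config(n_iter = 3000, burn_in = 500, thin = 2,
                                    seed = 7))
  expect_gt(cor(fr$gebv, fg$gebv), 0.98)
  fg2 <- fit_gblup(y, G, engine = "gibbs",
                   cfg = mcmc_config(n_iter = 1000, burn_in = 200, thin = 2,
                                     seed = 7))
  fg3 <- fit_gblup(y, G, engine = "gibbs",
                   cfg = mcmc_config(n_iter = 1000, burn_in = 200, thin = 2,
                                     seed = 7))
  expect_identical(fg2$gebv, fg3$gebv)
})

test_that("MAS-augmented models degenerate correctly at the boundaries", {
  g <- random_geno(30, 80, seed = 25)
  set.seed(25)
  y <- stats::setNames(rnorm(30), rownames(g$dosage))
  G <- grm_trace_norm(g)
  empty_M <- g$dosage[, integer(0), drop = FALSE]
  f0 <- fit_mas_gp(y, empty_M, G)
  f1 <- fit_gblup(y, G)
  expect_equal(f0$gebv, f1$gebv, tolerance = 1e-10)
  expect_equal(f0$method, "MAS_GBLUP")

  Msub <- g$dosage[, 1:3]
  fm <- fit_mas_gp(y, Msub, NULL, effect = "A")
  fm2 <- fit_mas(y, Msub, "A")
  expect_equal(unname(fm$gebv), unname(fm2$gebv), tolerance = 1e-12)
})

test_that("fixed-marker signal is absorbed by M, leaving little kernel variance", {
  g <- random_geno(120, 60, seed = 26)
  Z <- code_additive(g$dosage)
  set.seed(26)
  y <- stats::setNames(3 + 1.5 * Z[, 5] - 1.0 * Z[, 9] + rnorm(120, 0, 0.3),
                       rownames(g$dosage))
  M <- g$dosage[, c(5, 9)]
  GW <- grm_trace_norm(g, markers = setdiff(colnames(g$dosage),
                                            colnames(M)))
  fit <- fit_mas_gp(y, M, GW, effect = "A")
  expect_equal(unname(fit$f), c(1.5, -1.0), tolerance = 0.15)
  expect_lt(fit$sigma2_g / var(y), 0.2)
  # adding the fixed markers reduces the random genetic variance
  fit_all <- fit_gblup(y, grm_trace_norm(g))
  expect_lt(fit$sigma2_g, fit_all$sigma2_g)
})

test_that("BayesB finds a lone causal marker and is seed-reproducible", {
  g <- random_geno(80, 40, seed = 27)
  Z <- code_additive(g$dosage)
  y <- stats::setNames(2 + 1.8 * Z[, 7], rownames(g$dosage))
  cfg <- mcmc_config(n_iter = 3000, burn_in = 500, thin = 2, seed = 5)
  fit <- fit_bayesb(y, g, cfg)
  ols <- coef(lm(y ~ Z[, 7]))[2]
  expect_lt(abs(fit$b[7] - ols) / abs(ols), 0.05)
  expect_lt(max(abs(fit$b[-7])), 0.15)
  fit2 <- fit_bayesb(y, g, cfg)
  expect_identical(fit$b, fit2$b)
})

test_that("BayesB shrinks to near-zero signal on a null phenotype", {
  g <- random_geno(80, 150, seed = 28)
  set.seed(28)
  y <- stats::setNames(rnorm(80), rownames(g$dosage))
  fit <- fit_bayesb(y, g, mcmc_config(n_iter = 2000, burn_in = 400,
                                      thin = 2, seed = 6))
  expect_lt(var(fit$gebv), 0.4 * var(y))
  expect_lt(mean(fit$prob_in), 0.5)
})

test_that("BayesB with the spike disabled matches a Bayesian ridge oracle", {
  g <- random_geno(50, 100, seed = 29)
  Z <- code_additive(g$dosage)
  set.seed(29)
  y <- stats::setNames(drop(Z %*% rnorm(100, 0, 0.2)) + rnorm(50, 0, 0.5),
                       rownames(g$dosage))
  cfg <- mcmc_config(n_iter = 4000, burn_in = 1000, thin = 2, seed = 8)
  fit <- fit_bayesb(y, g, cfg, pi_fixed = 0)

  # oracle: joint-draw ridge Gibbs with a single common marker variance
  set.seed(99)
  n <- 50; m <- 100
  b <- rep(0, m); mu <- mean(y); s2e <- var(y) / 2; s2b <- 0.04
  df0 <- 5
  Sb <- 0.5 * var(y) * (df0 + 2) / (df0 * sum(apply(Z, 2, var)))
  Se <- 0.5 * var(y) * (df0 + 2) / df0
  ZtZ <- crossprod(Z)
  bsum <- rep(0, m); nk <- 0
  for (it in 1:4000) {
    C <- ZtZ + diag(s2e / s2b, m)
    ch <- chol(C)
    rhs <- crossprod(Z, y - mu)
    b <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE) +
                     rnorm(m) * sqrt(s2e))
    e <- y - mu - drop(Z %*% b)
    mu <- mean(e) + mu + rnorm(1, 0, sqrt(s2e / n))
    e <- y - mu - drop(Z %*% b)
    s2b <- (sum(b^2) + df0 * Sb) / rchisq(1, df0 + m)
    s2e <- (sum(e^2) + df0 * Se) / rchisq(1, df0 + n)
    if (it > 1000) { bsum <- bsum + b; nk <- nk + 1 }
  }
  b_or <- bsum / nk
  gebv_or <- drop(Z %*% b_or)
  expect_gt(cor(fit$gebv, gebv_or), 0.97)
  expect_lt(mean(abs(fit$b - b_or)), 0.05)
})

test_that("cross-validation scores a perfect predictor at 1 and noise near 0", {
  set.seed(30)
  y <- stats::setNames(rnorm(60), paste0("S", 1:60))
  perfect <- function(ym) new_gp_fit_for_test(y)
  cvp <- cross_validate(y, perfect, n_reps = 5, seed = 1)
  expect_equal(cvp$mean_pa, 1, tolerance = 1e-12)

  noise <- function(ym) {
    gv <- stats::setNames(rnorm(length(ym)), names(ym))
    new_gp_fit_for_test(gv)
  }
  cvn <- cross_validate(y, noise, n_reps = 50, seed = 2)
  se <- cvn$sd_pa / sqrt(50)
  expect_lt(abs(cvn$mean_pa), 2 * se + 0.1)
  expect_equal(nrow(cvn$reps), 50)
  expect_equal(cvn$mean_pa, mean(cvn$reps$r, na.rm = TRUE))
})

test_that("GBLUP predictive ability on an additive trait is in a plausible band", {
  pas <- vapply(1:10, function(s) {
    pan <- small_panel(seed = 300 + s, n1 = 22, n2 = 15, m = 400,
                       n_hyb = 400, dominance_ratio = 0.2)
    sim <- simulate_phenotypes(pan$hybrids, pan$design, pan$cfg)
    y <- entry_phenotype(sim$truth, h2 = 0.5, seed = s, what = "g_in")
    gp_cross_validate(y, "gblup", pan$hybrids, n_reps = 5,
                      seed = s)$mean_pa
  }, numeric(1))
  expect_gt(mean(pas), 0.3)
  expect_lt(mean(pas), 0.7)
})
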