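test_that("scan with no kinship and no PCs equals per-marker OLS", {
  g <- random_geno(50, 20, seed = 31)
  set.seed(31)
  y <- stats::setNames(rnorm(50), rownames(g$dosage))
  cfg <- gwas_config("A", "none", n_pc = 0)
  sc <- gwas_scan(y, g, cfg)
  Z <- code_additive(g$dosage)
  for (j in c(1, 7, 20)) {
    fit <- summary(lm(y ~ Z[, j]))
    expect_equal(sc$beta[j], unname(coef(fit)[2, 1]), tolerance = 1e-8)
    expect_equal(sc$p[j], unname(coef(fit)[2, 4]), tolerance = 1e-8)
  }
})

test_that("AD scan tests both effects and falls back where dominance is absent", {
  d <- random_geno(60, 10, seed = 32)$dosage
  d[, 4][d[, 4] == 1] <- 0          # no heterozygotes at marker 4
  g <- tiny_geno(d)
  set.seed(32)
  y <- stats::setNames(rnorm(60), rownames(d))
  cfg <- gwas_config("AD", "none", n_pc = 0)
  sc <- gwas_scan(y, g, cfg)
  expect_setequal(unique(sc$effect), c("A", "D"))
  a4 <- sc[sc$marker_id == "M4" & sc$effect == "A", ]
  d4 <- sc[sc$marker_id == "M4" & sc$effect == "D", ]
  expect_true(is.na(d4$p))          # zero-variance dominance coding skipped
  scA <- gwas_scan(y, g, gwas_config("A", "none", n_pc = 0))
  expect_equal(a4$beta, scA$beta[scA$marker_id == "M4"], tolerance = 1e-10)

  # full AD fit matches lm with both codings, marginal t-tests
  Z <- code_additive(d); W <- code_dominance(d)
  fit <- summary(lm(y ~ Z[, 2] + W[, 2]))
  expect_equal(sc$beta[sc$marker_id == "M2" & sc$effect == "A"],
               unname(coef(fit)[2, 1]), tolerance = 1e-8)
  expect_equal(sc$p[sc$marker_id == "M2" & sc$effect == "D"],
               unname(coef(fit)[3, 4]), tolerance = 1e-8)
})

test_that("a planted QTL is detected against the permutation threshold", {
  hit <- vapply(1:20, function(s) {
    g <- random_geno(300, 200, seed = 400 + s)
    Z <- code_additive(g$dosage)
    set.seed(400 + s)
    zq <- Z[, 50]  # scaled to explain ~25% of the phenotypic variance
    y <- stats::setNames(zq * sqrt(0.25 * 1 / var(zq)) + rnorm(300, 0, 0.87),
                         rownames(g$dosage))
    cfg <- gwas_config("A", "none", n_pc = 0, n_perm = 100, seed = s)
    nul <- gwas_null(y, g, cfg)
    sc <- gwas_scan(y, g, cfg, null = nul)
    thr <- permutation_threshold(y, g, cfg, null = nul)
    sc$p[50] <= thr
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("polygenic control with the additive kinship calibrates a structured trait", {
  cfg0 <- sim_config(n_parents_group1 = 60, n_parents_group2 = 60,
                     n_markers = 600, group_divergence = 0.3,
                     n_hybrids = 100, seed = 33)
  par <- simulate_parents(cfg0)
  set.seed(33)
  yl <- stats::setNames(2 * (par$groups == "group1") + rnorm(120, 0, 1),
                        rownames(par$dosage))
  sc_none <- gwas_scan(yl, par, gwas_config("A", "none", n_pc = 0))
  sc_pc <- gwas_scan(yl, par, gwas_config("A", "none", n_pc = 1))
  expect_gt(attr(sc_none, "lambda"), 1.3)
  expect_lt(abs(attr(sc_pc, "lambda") - 1),
            abs(attr(sc_none, "lambda") - 1))
  best <- select_model(list(sc_none, sc_pc))
  expect_equal(attr(best, "config")$n_pc, 1)
  single <- select_model(list(sc_none))
  expect_equal(attr(single, "lambda"), attr(sc_none, "lambda"))
})

test_that("mixed-model scan with kinship matches GLS at the null variance ratio", {
  g <- random_geno(80, 100, seed = 34)
  GA <- grm_additive(g)
  set.seed(34)
  u <- drop(t(chol(unclass(GA) + diag(1e-6, 80))) %*% rnorm(80))
  y <- stats::setNames(u + rnorm(80), rownames(g$dosage))
  cfg <- gwas_config("A", "A", n_pc = 0)
  nul <- gwas_null(y, g, cfg)
  sc <- gwas_scan(y, g, cfg, null = nul)
  # oracle GLS for one marker at the cached covariance
  delta <- nul$varcomp$variance[2] / nul$varcomp$variance[1]
  V <- unclass(GA) + delta * diag(80)
  Vi <- solve(V)
  for (j in c(3, 42)) {
    X <- cbind(1, code_additive(g$dosage)[, j])
    bhat <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    expect_equal(sc$beta[j], bhat[2], tolerance = 1e-6)
  }
})

test_that("two-kernel null model recovers variance ratios and flags duplicates", {
  g <- random_geno(200, 300, seed = 35)
  GA <- grm_additive(g)
  GD <- grm_dominance(g)
  set.seed(35)
  ua <- drop(t(chol(unclass(GA) + diag(1e-6, 200))) %*% rnorm(200)) * 1
  ud <- drop(t(chol(unclass(GD) + diag(1e-6, 200))) %*% rnorm(200)) * 0.8
  y <- stats::setNames(ua + ud + rnorm(200), rownames(g$dosage))
  cfg <- gwas_config("AD", "AD", n_pc = 0)
  nul <- gwas_null(y, g, cfg)
  expect_equal(nrow(nul$varcomp), 3)
  expect_true(all(nul$varcomp$variance >= 0))
  sc <- gwas_scan(y, g, cfg, null = nul)
  expect_equal(nrow(sc), 2 * 300)
})

test_that("permutation threshold is the alpha-order statistic and monotone in alpha", {
  g <- random_geno(60, 50, seed = 36)
  set.seed(36)
  y <- stats::setNames(rnorm(60), rownames(g$dosage))
  cfg5 <- gwas_config("A", "none", n_pc = 0, n_perm = 100, alpha = 0.05,
                      seed = 4)
  thr5 <- permutation_threshold(y, g, cfg5)
  minp <- attr(thr5, "min_p")
  expect_equal(as.numeric(thr5), sort(minp)[5])
  cfg1 <- gwas_config("A", "none", n_pc = 0, n_perm = 100, alpha = 0.02,
                      seed = 4)
  thr1 <- permutation_threshold(y, g, cfg1)
  expect_lte(as.numeric(thr1), as.numeric(thr5))
  expect_error(permutation_threshold(
    y, g, gwas_config("A", "none", n_perm = 30, alpha = 0.02, seed = 1)),
    "1/alpha")
})

test_that("allele substitution effect and marker heritabilities follow the formulas", {
  expect_equal(ase(-9.56, 10.60, 0.08), -9.56 + 10.60 * (0.92 - 0.08))
  expect_equal(ase(3, 0, 0.2), 3)
  expect_equal(ase(3, 5, 0.5), 3)

  expect_error(marker_h2(0.2, var_g = 0, beta = 1), "var_g")
  expect_equal(marker_h2(0.3, var_g = 10, beta = 0)$h2, 0)

  # AD mode with d = 0 reduces to the additive formula; dominance part 0
  h_ad <- marker_h2(0.2, var_g = 5, a = 1.5, d = 0, mode = "AD")
  h_a <- marker_h2(0.2, var_g = 5, beta = 1.5)
  expect_equal(h_ad$h2[h_ad$effect == "A"], h_a$h2)
  expect_equal(h_ad$h2[h_ad$effect == "D"], 0)
})

test_that("marker heritability at true effects matches realised variance fractions", {
  g <- random_geno(1000, 5, seed = 37)
  Z <- code_additive(g$dosage)
  set.seed(37)
  beta <- 0.8
  y <- beta * Z[, 2] + rnorm(1000, 0, 1)
  p <- mean(g$dosage[, 2]) / 2
  h2 <- marker_h2(p, var_g = var(y), beta = beta)$h2
  realised <- var(beta * Z[, 2]) / var(y)
  expect_lt(abs(h2 - realised) / realised, 0.2)
})

test_that("line and hybrid scans disagree on a dominance-heavy trait", {
  overlaps <- vapply(1:5, function(s) {
    pan <- small_panel(seed = 500 + s, n1 = 20, n2 = 14, m = 400,
                       n_hyb = 200, dominance_ratio = 8)
    sim <- simulate_phenotypes(pan$hybrids, pan$design, pan$cfg)
    y <- entry_phenotype(sim$truth, h2 = 0.5, seed = s)
    lp <- line_phenotypes(pan$parents, sim$qtl, pan$cfg)
    yl <- stats::setNames(lp$value, lp$sample_id)
    k <- 10
    sl <- gwas_scan(yl, pan$parents, gwas_config("A", "none", n_pc = 1))
    sh <- gwas_scan(y, pan$hybrids, gwas_config("AD", "none", n_pc = 1))
    top_l <- head(dplyr::arrange(tibble::as_tibble(sl), p)$marker_id, k)
    top_h <- head(unique(dplyr::arrange(tibble::as_tibble(sh),
                                        p)$marker_id), k)
    length(intersect(top_l, top_h))
  }, numeric(1))
  # chance overlap of two 10-marker sets out of ~400 is ~0.25 markers
  expect_lt(mean(overlaps), 2)
})
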