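test_that("simulated parents are homozygous, seeded and Fst-calibrated", {
  cfg <- sim_config(n_parents_group1 = 30, n_parents_group2 = 30,
                    n_markers = 2000, n_chromosomes = 10,
                    group_divergence = 0.3, maf_low = 0.1, ld_block = 4,
                    n_hybrids = 100, seed = 11)
  g1 <- simulate_parents(cfg)
  g2 <- simulate_parents(cfg)
  expect_false(any(g1$dosage == 1))
  expect_identical(g1$dosage, g2$dosage)

  # independent Hudson/Weir-Cockerham-style two-population Fst estimator on
  # the realised allele frequencies, treating each inbred as one haplotype
  grp <- g1$groups
  p1 <- colMeans(g1$dosage[grp == "group1", ]) / 2
  p2 <- colMeans(g1$dosage[grp == "group2", ]) / 2
  n1 <- sum(grp == "group1"); n2 <- sum(grp == "group2")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- sum(num) / sum(den)
  expect_lt(abs(fst - 0.3), 0.05)
})

test_that("marker positions increase strictly within chromosome", {
  cfg <- sim_config(n_parents_group1 = 5, n_parents_group2 = 5,
                    n_markers = 200, n_chromosomes = 3, n_hybrids = 10,
                    seed = 2)
  g <- simulate_parents(cfg)
  by_chr <- split(g$map$pos, g$map$chrom)
  expect_true(all(vapply(by_chr, function(x) all(diff(x) > 0), logical(1))))
})

test_that("blockwise copying induces within-block LD", {
  cfg <- sim_config(n_parents_group1 = 40, n_parents_group2 = 40,
                    n_markers = 500, n_chromosomes = 5, ld_block = 10,
                    ld_copy = 0.9, n_hybrids = 100, seed = 4)
  g <- simulate_parents(cfg)
  expect_gt(mean_adjacent_r2_oracle(g), 0.4)
})

test_that("partial diallel sampling is exhaustive, unique and bounded", {
  par4 <- tiny_geno(matrix(0, 4, 2), role = "parents")
  par4$groups <- stats::setNames(c("group1", "group1", "group2", "group2"),
                                 rownames(par4$dosage))
  des <- make_diallel(par4, 4, seed = 1)
  expect_equal(nrow(des), 4)
  expect_equal(nrow(dplyr::distinct(des, parent1, parent2)), 4)
  expect_error(make_diallel(par4, 5, seed = 1), "exceeds")

  cfg <- sim_config(n_parents_group1 = 35, n_parents_group2 = 15,
                    n_markers = 50, n_qtl = 20, n_hybrids = 100, seed = 3)
  par <- simulate_parents(cfg)
  expect_error(make_diallel(par, 906, seed = 1, allow_intragroup = FALSE),
               "525")
  des5 <- make_diallel(par, 500, seed = 1, allow_intragroup = FALSE)
  expect_equal(nrow(dplyr::distinct(des5, parent1, parent2)), 500)
  usage <- attr(des5, "usage")
  expect_equal(sum(usage$n_crosses), 1000)
})

test_that("phenotype generator hits the target plot heritability and regime gap", {
  h2 <- vapply(1:10, function(s) {
    pan <- small_panel(seed = s, n1 = 12, n2 = 8, m = 300, n_hyb = 100,
                       h2_plot = 0.25)
    sim <- simulate_phenotypes(pan$hybrids, pan$design, pan$cfg)
    vg <- var(c(sim$truth$g_in, sim$truth$g_ln))
    vg / (vg + sim$varcomp$sigma2_e + sim$varcomp$sigma2_check_env)
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.25), 0.05)

  gaps <- vapply(21:25, function(s) {
    pan <- small_panel(seed = s, n1 = 12, n2 = 8, m = 300, n_hyb = 150,
                       regime_effect = 0.87)
    sim <- simulate_phenotypes(pan$hybrids, pan$design, pan$cfg)
    hyb_plots <- dplyr::filter(sim$plots, !is_check)
    mean(hyb_plots$yield[hyb_plots$n_regime == "IN"]) -
      mean(hyb_plots$yield[hyb_plots$n_regime == "LN"])
  }, numeric(1))
  expect_lt(abs(mean(gaps) - 0.87), 0.15)
})

test_that("dominance_ratio controls the dominance variance exactly at zero", {
  pan <- small_panel(seed = 5, n1 = 10, n2 = 8, m = 200, n_hyb = 60,
                     dominance_ratio = 0)
  sim <- simulate_phenotypes(pan$hybrids, pan$design, pan$cfg)
  expect_true(all(sim$truth$dominance == 0))
  expect_true(all(sim$qtl$d == 0))
  expect_equal(sim$truth$g_in, sim$truth$additive, tolerance = 1e-12)
})

test_that("hybrid allele frequency equals the mean of parental pair frequencies", {
  pan <- small_panel(seed = 6, n1 = 8, n2 = 6, m = 150, n_hyb = 40)
  des <- pan$design
  par <- pan$parents$dosage
  hyb <- make_hybrid_genotypes(pan$parents, des)$dosage
  expected <- (colMeans(par[des$parent1, , drop = FALSE]) +
                 colMeans(par[des$parent2, , drop = FALSE])) / 2 / 2
  expect_equal(colMeans(hyb) / 2, expected, tolerance = 1e-12)
})

test_that("line values are purely additive and reach the configured heritability", {
  pan <- small_panel(seed = 7, n1 = 12, n2 = 8, m = 200, n_hyb = 50,
                     line_h2 = 1)
  sim <- simulate_phenotypes(pan$hybrids, pan$design, pan$cfg)
  qtl_in_panel <- sim$qtl[sim$qtl$marker_id %in%
                            colnames(pan$parents$dosage), ]
  lp <- line_phenotypes(pan$parents, qtl_in_panel, pan$cfg)
  expect_equal(cor(lp$value, lp$genetic), 1)
  Z <- pan$parents$dosage[, qtl_in_panel$marker_id] - 1
  expect_equal(lp$genetic, drop(Z %*% qtl_in_panel$a))
})

test_that("a dominance-only trait leaves the parental lines silent", {
  # lines express only additive QTL content: with a = 0 everywhere their
  # values are pure noise and a line scan should find nothing, while the
  # hybrids still segregate genetically
  hits <- vapply(1:20, function(s) {
    pan <- small_panel(seed = s + 100, n1 = 15, n2 = 10, m = 300,
                       n_hyb = 60)
    sim <- simulate_phenotypes(pan$hybrids, pan$design, pan$cfg)
    qtl0 <- sim$qtl
    qtl0$a[] <- 0
    expect_gt(var(sim$truth$g_in), 0)
    lp <- line_phenotypes(pan$parents, qtl0, pan$cfg)
    yl <- stats::setNames(lp$value, lp$sample_id)
    cfgw <- gwas_config("A", "none", n_pc = 0, n_perm = 50, seed = s)
    nul <- gwas_null(yl, pan$parents, cfgw)
    sc <- gwas_scan(yl, pan$parents, cfgw, null = nul)
    thr <- permutation_threshold(yl, pan$parents, cfgw, null = nul)
    nrow(significant_markers(sc, thr)) > 0
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})
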