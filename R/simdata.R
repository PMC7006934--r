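#' Simulation configuration
#'
#' Defines the synthetic study: two heterotic groups of fully homozygous
#' inbred parents, a partial diallel of single-cross hybrids, and unreplicated
#' augmented-block yield trials under two nitrogen regimes. Defaults describe
#' the design this package was written for: 35 + 15 parents, 906 hybrids,
#' trials at 2 sites x 2 years per regime with incomplete blocks of 16 test
#' entries plus 2 replicated checks, a polygenic trait with additive and
#' dominance action and plot-level heritability around 0.22.
#'
#' @param n_parents_group1,n_parents_group2 parents per heterotic group.
#' @param n_markers,n_chromosomes marker panel size and chromosome count.
#' @param group_divergence Fst-like divergence between the two groups in
#'   `[0, 1)`; group frequencies follow a Balding-Nichols model around a
#'   shared ancestral frequency.
#' @param maf_low,maf_high bounds of the ancestral allele-frequency draw,
#'   both in `(0, 0.5]`.
#' @param ld_block,ld_copy markers are laid down in blocks of `ld_block`
#'   consecutive markers; within a block each marker copies the block's core
#'   allele with probability `ld_copy`, which induces within-block linkage
#'   disequilibrium of roughly `ld_copy^2` (r-squared).
#' @param n_hybrids single crosses to sample from the diallel.
#' @param allow_intragroup also sample crosses within a heterotic group. The
#'   default is `TRUE` because 906 hybrids from 35 + 15 parents exceeds the
#'   35 x 15 inter-group pairs, so the mating design must include some
#'   intra-group crosses.
#' @param n_qtl causal markers for the trait.
#' @param dominance_ratio target ratio Var_D / Var_A of the dominance to the
#'   additive genotypic variance among hybrids (0 = purely additive;
#'   `Inf` = purely dominance, all additive effects exactly zero).
#' @param sigma_g genetic standard deviation of the hybrid genotypic values
#'   under the ideal-N regime (Mg/ha).
#' @param gen_cor genetic correlation between the low-N and ideal-N
#'   genotypic values.
#' @param h2_plot target plot-level heritability in `(0, 1)`.
#' @param n_sites,n_years environments are the site x year combinations,
#'   crossed with the two nitrogen regimes.
#' @param block_size test entries (hybrids) per incomplete block.
#' @param n_checks replicated check entries present in every block.
#' @param grand_mean mean yield under the ideal-N regime (Mg/ha).
#' @param regime_effect mean yield drop from ideal to low N (Mg/ha).
#' @param sigma_env,sigma_block,sigma_check_env standard deviations of the
#'   environment, block-within-environment and check-by-environment effects
#'   (Mg/ha).
#' @param line_h2 heritability of the parental-line trait values returned by
#'   [line_phenotypes()].
#' @param seed integer; fully determines every simulated quantity.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_parents_group1 = 35, n_parents_group2 = 15,
                       n_markers = 34571, n_chromosomes = 10,
                       group_divergence = 0.2,
                       maf_low = 0.05, maf_high = 0.5,
                       ld_block = 10, ld_copy = 0.9,
                       n_hybrids = 906, allow_intragroup = TRUE,
                       n_qtl = 200, dominance_ratio = 1,
                       sigma_g = 0.45, gen_cor = 0.8,
                       h2_plot = 0.22,
                       n_sites = 2, n_years = 2,
                       block_size = 16, n_checks = 2,
                       grand_mean = 7.37, regime_effect = 0.87,
                       sigma_env = 0.5, sigma_block = 0.5,
                       sigma_check_env = 0.25,
                       line_h2 = 0.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_parents_group1", "n_parents_group2", "n_markers",
              "n_chromosomes", "n_hybrids", "n_qtl", "n_sites", "n_years",
              "block_size", "n_checks")
  for (nm in counts) {
    if (cfg[[nm]] < 1) stop(nm, " must be >= 1")
  }
  if (cfg$h2_plot <= 0 || cfg$h2_plot >= 1) stop("h2_plot must be in (0, 1)")
  if (cfg$group_divergence < 0 || cfg$group_divergence >= 1) {
    stop("group_divergence must be in [0, 1)")
  }
  if (cfg$maf_low <= 0 || cfg$maf_high > 0.5 || cfg$maf_low > cfg$maf_high) {
    stop("maf bounds must satisfy 0 < maf_low <= maf_high <= 0.5")
  }
  if (cfg$dominance_ratio < 0) stop("dominance_ratio must be >= 0")
  if (cfg$n_qtl > cfg$n_markers) stop("n_qtl cannot exceed n_markers")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

#' Simulate two heterotic groups of fully homozygous parents
#'
#' Ancestral allele frequencies are drawn uniformly inside the configured MAF
#' band (with a random choice of which allele is coded 2); each group's
#' frequency is then a Balding-Nichols Beta draw around the ancestral value
#' with divergence parameter `group_divergence`. Parents are fully homozygous
#' (dosages 0/2), and within-chromosome linkage disequilibrium comes from a
#' blockwise copying model.
#'
#' @param cfg a [sim_config()].
#' @return A [geno] object with `role = "parents"`, group labels attached,
#'   and the per-group frequencies in `attr(, "group_freqs")`.
#' @export
simulate_parents <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$n_markers
  p_anc <- stats::runif(m, cfg$maf_low, cfg$maf_high)
  flip <- stats::runif(m) < 0.5
  p_anc[flip] <- 1 - p_anc[flip]

  fst <- cfg$group_divergence
  draw_group <- function() {
    if (fst == 0) return(p_anc)
    a <- p_anc * (1 - fst) / fst
    b <- (1 - p_anc) * (1 - fst) / fst
    stats::rbeta(m, a, b)
  }
  p1 <- draw_group()
  p2 <- draw_group()

  # markers within an LD block share the frequency drawn at the block core,
  # so allele copying leaves every marker's marginal frequency intact
  block_id <- ceiling(seq_len(m) / cfg$ld_block)
  core_idx <- match(block_id, block_id)      # first marker of each block
  p_anc <- p_anc[core_idx]
  p1 <- p1[core_idx]
  p2 <- p2[core_idx]

  n1 <- cfg$n_parents_group1
  n2 <- cfg$n_parents_group2
  ids <- c(paste0("F", seq_len(n1)), paste0("D", seq_len(n2)))
  groups <- stats::setNames(rep(c("group1", "group2"), c(n1, n2)), ids)

  draw_pool <- function(pfreq, n) {
    raw <- matrix(stats::runif(n * m) < rep(pfreq, each = n), n, m)
    core <- raw[, core_idx, drop = FALSE]
    copy <- matrix(stats::runif(n * m) < cfg$ld_copy, n, m)
    allele <- ifelse(copy, core, raw)
    2 * allele
  }
  dosage <- rbind(draw_pool(p1, n1), draw_pool(p2, n2))
  rownames(dosage) <- ids

  chrom <- rep(seq_len(cfg$n_chromosomes), length.out = m)
  chrom <- sort(chrom)
  pos <- stats::ave(rep(1, m), chrom,
                    FUN = function(x) cumsum(sample(100:10000, length(x),
                                                    replace = TRUE)))
  map <- tibble::tibble(marker_id = paste0("mk", seq_len(m)),
                        chrom = chrom, pos = as.integer(pos))
  colnames(dosage) <- map$marker_id
  g <- geno(dosage, map, role = "parents", groups = groups)
  attr(g, "group_freqs") <- tibble::tibble(marker_id = map$marker_id,
                                           p_anc = p_anc, p1 = p1, p2 = p2)
  g
}

#' Sample a partial diallel of single crosses
#'
#' Draws `n_hybrids` unique parent pairs. By default pairs may come from
#' within as well as between the heterotic groups; with
#' `allow_intragroup = FALSE` only inter-group crosses are eligible.
#'
#' @param parents a [geno] object of parents carrying group labels.
#' @param n_hybrids number of crosses to draw.
#' @param seed integer seed.
#' @param allow_intragroup also allow crosses within a group.
#' @return A tibble (`hybrid_id`, `parent1`, `parent2`) of unique pairs; the
#'   per-parent usage table is `attr(, "usage")`.
#' @export
make_diallel <- function(parents, n_hybrids, seed = 1L,
                         allow_intragroup = FALSE) {
  stopifnot(inherits(parents, "geno"))
  ids <- rownames(parents$dosage)
  grp <- parents$groups
  if (is.null(grp)) grp <- stats::setNames(rep("group1", length(ids)), ids)
  pairs <- t(utils::combn(ids, 2))
  if (!allow_intragroup) {
    keep <- grp[pairs[, 1]] != grp[pairs[, 2]]
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (n_hybrids > nrow(pairs)) {
    stop(sprintf("n_hybrids = %d exceeds the %d available %s pairs",
                 n_hybrids, nrow(pairs),
                 if (allow_intragroup) "distinct" else "inter-group"))
  }
  set.seed(seed)
  take <- sample.int(nrow(pairs), n_hybrids)
  des <- tibble::tibble(
    hybrid_id = sprintf("H%04d", seq_len(n_hybrids)),
    parent1 = pairs[take, 1],
    parent2 = pairs[take, 2]
  )
  usage <- tibble::tibble(parent = c(des$parent1, des$parent2)) |>
    dplyr::count(.data$parent, name = "n_crosses") |>
    dplyr::arrange(dplyr::desc(.data$n_crosses))
  attr(des, "usage") <- usage
  des
}

#' Simulate plot-level phenotypes for an augmented-block hybrid trial
#'
#' Picks `n_qtl` causal markers, gives them additive effects on the
#' \{-1,0,1\} coding and dominance deviations on the heterozygote indicator
#' scaled so the realised dominance/additive variance ratio among hybrids
#' matches `dominance_ratio`, builds ideal-N genotypic values and correlated
#' low-N values, and lays hybrids out in unreplicated augmented blocks
#' (each block carries every check) across `n_sites` x `n_years`
#' environments and two nitrogen regimes. The residual standard deviation is
#' chosen so the plot-level heritability among hybrid plots equals
#' `h2_plot`.
#'
#' @param hybrids a [geno] object of hybrid genotypes (see
#'   [make_hybrid_genotypes()]).
#' @param design the diallel design tibble from [make_diallel()].
#' @param cfg a [sim_config()].
#' @return A list with `plots` (tibble of plot records: `entry_id`,
#'   `is_check`, `site`, `year`, `n_regime`, `block_id`, `yield`), `truth`
#'   (per-hybrid additive, dominance and per-regime genotypic values plus
#'   true LNTI), `qtl` (per-QTL effects and frequencies) and `varcomp` (the
#'   generating variance components).
#' @export
simulate_phenotypes <- function(hybrids, design, cfg) {
  stopifnot(inherits(hybrids, "geno"), inherits(cfg, "sim_config"))
  if (cfg$n_qtl > ncol(hybrids$dosage)) stop("n_qtl cannot exceed n_markers")
  set.seed(cfg$seed + 1L)
  dos <- hybrids$dosage
  n <- nrow(dos)

  qtl_idx <- sort(sample.int(ncol(dos), cfg$n_qtl))
  Zq <- dos[, qtl_idx, drop = FALSE] - 1
  Wq <- (dos[, qtl_idx, drop = FALSE] == 1) * 1
  a <- stats::rnorm(cfg$n_qtl)
  d <- stats::rnorm(cfg$n_qtl)
  A <- drop(Zq %*% a)
  D <- drop(Wq %*% d)
  if (is.infinite(cfg$dominance_ratio)) {
    a <- rep(0, cfg$n_qtl)           # purely dominance architecture
    A <- rep(0, n)
  } else if (cfg$dominance_ratio == 0 || stats::var(D) == 0) {
    d <- rep(0, cfg$n_qtl)
    D <- rep(0, n)
  } else {
    s <- sqrt(cfg$dominance_ratio * stats::var(A) / stats::var(D))
    d <- d * s
    D <- D * s
  }
  tot <- A + D
  sc <- cfg$sigma_g / stats::sd(tot)
  a <- a * sc; d <- d * sc; A <- A * sc; D <- D * sc
  g_in <- A + D - mean(A + D)
  # low-N genotypic values arise from per-QTL effects correlated with the
  # ideal-N effects, so both regimes' genetic values are marker-determined
  rho <- cfg$gen_cor
  sd_a <- sqrt(mean(a^2)); sd_d <- sqrt(mean(d^2))
  a_ln <- rho * a + sqrt(1 - rho^2) * stats::rnorm(cfg$n_qtl, 0, sd_a)
  d_ln <- if (sd_d > 0) {
    rho * d + sqrt(1 - rho^2) * stats::rnorm(cfg$n_qtl, 0, sd_d)
  } else d
  g_ln <- drop(Zq %*% a_ln + Wq %*% d_ln)
  g_ln <- g_ln - mean(g_ln)
  if (stats::sd(g_ln) > 0) g_ln <- g_ln * cfg$sigma_g / stats::sd(g_ln)

  mu_in <- cfg$grand_mean
  mu_ln <- cfg$grand_mean - cfg$regime_effect
  lnti_true <- (1 - (mu_ln + g_ln) / (mu_in + g_in)) * 100

  var_g <- stats::var(c(g_in, g_ln))
  sigma2_e <- var_g * (1 / cfg$h2_plot - 1) - cfg$sigma_check_env^2
  if (sigma2_e <= 0) {
    stop("h2_plot too high for the configured check-by-environment variance")
  }

  hyb_ids <- design$hybrid_id
  check_ids <- paste0("CHK", seq_len(cfg$n_checks))
  check_val <- seq(-0.5, 0.5, length.out = max(cfg$n_checks, 2))[
    seq_len(cfg$n_checks)] * cfg$sigma_g
  names(check_val) <- check_ids

  envs <- tidyr::expand_grid(site = paste0("site", seq_len(cfg$n_sites)),
                             year = 2016L + seq_len(cfg$n_years) - 1L)
  env_eff <- stats::rnorm(nrow(envs), 0, cfg$sigma_env)

  plots <- list()
  for (e in seq_len(nrow(envs))) {
    for (regime in c("IN", "LN")) {
      ord <- sample(hyb_ids)
      n_blocks <- ceiling(length(ord) / cfg$block_size)
      blk_of <- rep(seq_len(n_blocks), each = cfg$block_size)[
        seq_along(ord)]
      blk_eff <- stats::rnorm(n_blocks, 0, cfg$sigma_block)
      ce_eff <- stats::rnorm(cfg$n_checks, 0, cfg$sigma_check_env)
      names(ce_eff) <- check_ids
      mu <- if (regime == "IN") mu_in else mu_ln
      gval <- if (regime == "IN") {
        stats::setNames(g_in, hyb_ids)
      } else {
        stats::setNames(g_ln, hyb_ids)
      }
      hy <- tibble::tibble(
        entry_id = ord, is_check = FALSE,
        block = blk_of,
        g = gval[ord] + mu + env_eff[e] + blk_eff[blk_of]
      )
      ck <- tidyr::expand_grid(entry_id = check_ids,
                               block = seq_len(n_blocks)) |>
        dplyr::mutate(is_check = TRUE,
                      g = check_val[.data$entry_id] + mu + env_eff[e] +
                        blk_eff[.data$block] + ce_eff[.data$entry_id])
      both <- dplyr::bind_rows(hy, ck)
      both$yield <- both$g + stats::rnorm(nrow(both), 0, sqrt(sigma2_e))
      both$site <- envs$site[e]
      both$year <- envs$year[e]
      both$n_regime <- regime
      both$block_id <- sprintf("%s_%d_%s_b%02d", envs$site[e], envs$year[e],
                               regime, both$block)
      plots[[length(plots) + 1L]] <-
        both[, c("entry_id", "is_check", "site", "year", "n_regime",
                 "block_id", "yield")]
    }
  }
  plots <- dplyr::bind_rows(plots)
  plots$yield <- pmax(plots$yield, 0)

  p_freq <- colMeans(dos[, qtl_idx, drop = FALSE]) / 2
  list(
    plots = plots,
    truth = tibble::tibble(
      hybrid_id = hyb_ids, additive = A - mean(A), dominance = D - mean(D),
      g_in = g_in, g_ln = g_ln, lnti_true = lnti_true
    ),
    qtl = tibble::tibble(
      marker_id = colnames(dos)[qtl_idx], a = a, d = d, p = p_freq
    ),
    varcomp = tibble::tibble(
      sigma2_g = var_g, sigma2_e = sigma2_e,
      sigma2_check_env = cfg$sigma_check_env^2,
      sigma2_block = cfg$sigma_block^2, sigma2_env = cfg$sigma_env^2
    )
  )
}

#' Simulate parental-line trait values
#'
#' A fully homozygous line expresses only the additive part of each QTL
#' (there are no heterozygotes, so dominance deviations never materialise):
#' its genetic value is the sum of additive QTL contributions on the
#' \{-1,+1\} coding. Gaussian noise is added to reach the configured line
#' heritability `line_h2` (`line_h2 = 1` means no noise; a trait with all
#' additive effects zero yields pure noise with unit variance).
#'
#' @param parents a [geno] object of homozygous parents.
#' @param qtl the `qtl` tibble from [simulate_phenotypes()].
#' @param cfg a [sim_config()].
#' @return A tibble (`sample_id`, `value`, `genetic`).
#' @export
line_phenotypes <- function(parents, qtl, cfg) {
  stopifnot(inherits(parents, "geno"))
  if (any(parents$dosage == 1, na.rm = TRUE)) {
    stop("parents must be fully homozygous")
  }
  set.seed(cfg$seed + 2L)
  Z <- parents$dosage[, qtl$marker_id, drop = FALSE] - 1
  gen <- drop(Z %*% qtl$a)
  vg <- stats::var(gen)
  sd_e <- if (vg == 0) 1 else if (cfg$line_h2 >= 1) 0 else {
    sqrt(vg * (1 / cfg$line_h2 - 1))
  }
  tibble::tibble(
    sample_id = rownames(parents$dosage),
    value = gen + stats::rnorm(length(gen), 0, sd_e),
    genetic = gen
  )
}
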