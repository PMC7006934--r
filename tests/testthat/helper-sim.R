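# Shared fixture builders; everything is generated in code under fixed seeds.

tiny_geno <- function(dosage, role = "hybrids", chrom = NULL) {
  d <- as.matrix(dosage)
  if (is.null(rownames(d))) rownames(d) <- paste0("S", seq_len(nrow(d)))
  if (is.null(colnames(d))) colnames(d) <- paste0("M", seq_len(ncol(d)))
  map <- tibble::tibble(marker_id = colnames(d),
                        chrom = chrom %||% rep(1L, ncol(d)),
                        pos = seq_len(ncol(d)))
  geno(d, map, role = role)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random complete hybrid-like panel under HWE at given frequencies.
random_geno <- function(n, m, seed = 1, p = NULL, role = "hybrids") {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.9)
  d <- sapply(p, function(pp) rbinom(n, 2, pp))
  tiny_geno(d, role = role)
}

# Small end-to-end panel: parents -> diallel -> hybrids (QC'd).
small_panel <- function(seed = 1, n1 = 15, n2 = 10, m = 600, n_hyb = 120,
                        n_qtl = 40, ...) {
  cfg <- sim_config(n_parents_group1 = n1, n_parents_group2 = n2,
                    n_markers = m, n_chromosomes = 5, n_hybrids = n_hyb,
                    n_qtl = n_qtl, seed = seed, ...)
  parents <- simulate_parents(cfg)
  design <- make_diallel(parents, n_hyb, seed = seed,
                         allow_intragroup = TRUE)
  hybrids <- maf_filter(make_hybrid_genotypes(parents, design))$geno
  list(cfg = cfg, parents = parents, design = design, hybrids = hybrids)
}

# Entry-level phenotype from simulated truth at a target entry-mean h2.
entry_phenotype <- function(truth, h2 = 0.5, seed = 1,
                            what = c("lnti", "g_in")) {
  what <- match.arg(what)
  g <- switch(what, lnti = truth$lnti_true, g_in = truth$g_in)
  set.seed(seed + 10000L)
  e <- rnorm(length(g), 0, sqrt(var(g) * (1 / h2 - 1)))
  stats::setNames(g + e, truth$hybrid_id)
}

# Minimal gp_fit wrapper for hand-built predictors in CV tests.
new_gp_fit_for_test <- function(gebv) {
  structure(list(method = "oracle", mu = 0, gebv = gebv, f = NULL,
                 b = NULL, sigma2_g = NA_real_, sigma2_e = NA_real_),
            class = "gp_fit")
}

# Independent adjacent-pair r2, written without the package internals.
mean_adjacent_r2_oracle <- function(g) {
  r2 <- c()
  for (ch in unique(g$map$chrom)) {
    d <- g$dosage[, g$map$chrom == ch, drop = FALSE]
    if (ncol(d) < 2) next
    for (j in seq_len(ncol(d) - 1)) {
      r2 <- c(r2, suppressWarnings(cor(d[, j], d[, j + 1]))^2)
    }
  }
  mean(r2, na.rm = TRUE)
}

# Simulated augmented-design plots with known variance components, used for
# REML parameter-recovery checks.
sim_augmented <- function(seed, n_hyb = 200, n_checks = 2, block_size = 8,
                          n_env = 2, sigma2_b = 0.5, sigma2_e = 1.0) {
  set.seed(seed)
  hyb <- sprintf("H%03d", seq_len(n_hyb))
  chk <- paste0("CHK", seq_len(n_checks))
  gh <- stats::setNames(rnorm(n_hyb, 0, 1), hyb)
  gc <- stats::setNames(seq(-0.5, 0.5, length.out = n_checks), chk)
  rows <- list()
  for (e in seq_len(n_env)) {
    env_eff <- rnorm(1, 0, 0.5)
    ord <- sample(hyb)
    nb <- ceiling(n_hyb / block_size)
    blk <- rep(seq_len(nb), each = block_size)[seq_along(ord)]
    beff <- rnorm(nb, 0, sqrt(sigma2_b))
    df <- rbind(
      data.frame(entry_id = ord, is_check = FALSE, block = blk,
                 g = gh[ord] + env_eff + beff[blk]),
      do.call(rbind, lapply(seq_len(nb), function(b) {
        data.frame(entry_id = chk, is_check = TRUE, block = b,
                   g = gc[chk] + env_eff + beff[b])
      }))
    )
    df$yield <- 7 + df$g + rnorm(nrow(df), 0, sqrt(sigma2_e))
    df$site <- paste0("site", e); df$year <- 2016L
    df$n_regime <- "LN"
    df$block_id <- sprintf("s%d_b%02d", e, df$block)
    rows[[e]] <- df[, c("entry_id", "is_check", "site", "year", "n_regime",
                        "block_id", "yield")]
  }
  tibble::as_tibble(do.call(rbind, rows))
}
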