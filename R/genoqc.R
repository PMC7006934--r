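qc_report_row <- function(step, n_in, n_kept, detail = NA_character_) {
  tibble::tibble(step = step, n_input = n_in, n_removed = n_in - n_kept,
                 n_retained = n_kept, detail = detail)
}

#' Remove low call-rate markers
#'
#' @param g a [geno] object.
#' @param min_rate minimum fraction of non-missing calls, in `(0, 1]`.
#' @return A list with the filtered `geno` and a one-row `report` tibble.
#' @export
filter_call_rate <- function(g, min_rate = 0.95) {
  stopifnot(min_rate > 0, min_rate <= 1)
  cr <- colMeans(!is.na(g$dosage))
  keep <- cr >= min_rate
  if (!any(keep)) warning("no markers pass the call-rate filter")
  list(geno = geno_subset(g, markers = which(keep)),
       report = qc_report_row("call_rate", length(keep), sum(keep),
                              sprintf("min_rate=%g", min_rate)))
}

#' Drop markers carrying any heterozygote among inbred parents
#'
#' A heterozygous call in a fully inbred line is treated as a genotyping
#' artefact and the whole locus is discarded, leaving a panel where every
#' parental genotype is 0 or 2.
#'
#' @param parents a [geno] object with `role = "parents"`.
#' @return A list with the filtered `geno` and a `report` tibble.
#' @export
drop_het_markers <- function(parents) {
  if (parents$role != "parents") stop("drop_het_markers() expects parents")
  has_het <- colSums(parents$dosage == 1, na.rm = TRUE) > 0
  list(geno = geno_subset(parents, markers = which(!has_het)),
       report = qc_report_row("drop_het", length(has_het), sum(!has_het)))
}

#' Impute missing parental genotypes to homozygous classes
#'
#' Each missing entry is drawn as 0 or 2 with probability equal to the
#' marker's observed homozygote frequencies; the draw is seeded so the
#' imputation is reproducible.
#'
#' @param parents a [geno] object with no heterozygous calls.
#' @param seed integer seed for the imputation draws.
#' @return A [geno] object with no missing values.
#' @export
impute_homozygous <- function(parents, seed = 1L) {
  d <- parents$dosage
  if (any(d == 1, na.rm = TRUE)) {
    stop("heterozygous calls present; run drop_het_markers() first")
  }
  n_obs <- colSums(!is.na(d))
  if (any(n_obs == 0)) {
    stop("marker(s) entirely missing; frequencies cannot be estimated: ",
         paste(colnames(d)[n_obs == 0], collapse = ", "))
  }
  if (!anyNA(d)) return(parents)
  p2 <- colSums(d == 2, na.rm = TRUE) / n_obs   # P(homozygote 2)
  set.seed(seed)
  miss <- which(is.na(d), arr.ind = TRUE)
  d[miss] <- 2 * (stats::runif(nrow(miss)) < p2[miss[, 2]])
  geno(d, parents$map, role = parents$role, groups = parents$groups)
}

pairwise_r2 <- function(d) {
  # composite LD: squared dosage correlation; exact haplotype r2 for
  # homozygous inbreds
  suppressWarnings(stats::cor(d))^2
}

mean_adjacent_r2 <- function(g) {
  d <- g$dosage
  vals <- c()
  for (ch in unique(g$map$chrom)) {
    idx <- which(g$map$chrom == ch)
    if (length(idx) < 2) next
    a <- d[, idx[-length(idx)], drop = FALSE]
    b <- d[, idx[-1], drop = FALSE]
    r <- vapply(seq_len(ncol(a)), function(j) {
      suppressWarnings(stats::cor(a[, j], b[, j]))
    }, numeric(1))
    vals <- c(vals, r^2)
  }
  mean(vals, na.rm = TRUE)
}

prune_at_cut <- function(g, cut, window, step) {
  keep <- rep(TRUE, ncol(g$dosage))
  maf <- marker_stats(g)$maf
  for (ch in unique(g$map$chrom)) {
    idx <- which(g$map$chrom == ch)
    start <- 1
    repeat {
      win <- idx[seq(start, min(start + window - 1, length(idx)))]
      win <- win[keep[win]]
      if (length(win) >= 2) {
        r2 <- pairwise_r2(g$dosage[, win, drop = FALSE])
        r2[!is.finite(r2)] <- 0
        repeat {
          r2[lower.tri(r2, diag = TRUE)] <- 0
          hit <- which(r2 > cut, arr.ind = TRUE)
          if (nrow(hit) == 0) break
          i <- hit[1, 1]; j <- hit[1, 2]
          drop_local <- if (maf[win[i]] <= maf[win[j]]) i else j
          keep[win[drop_local]] <- FALSE
          r2[drop_local, ] <- 0
          r2[, drop_local] <- 0
        }
      }
      if (start + window - 1 >= length(idx)) break
      start <- start + step
    }
  }
  keep
}

#' LD-prune markers to a target mean adjacent r-squared
#'
#' Greedy windowed pruning in the style of PLINK's `indep-pairwise`: within a
#' sliding window, one marker of any pair whose r-squared exceeds a cut is
#' removed (the lower-MAF one first). The pairwise cut itself is found by
#' bisection so that the mean adjacent-marker r-squared of the retained panel
#' is as large as possible while not exceeding `target_mean_r2`.
#'
#' @param parents a [geno] object with complete data.
#' @param target_mean_r2 target upper bound for the mean adjacent-pair
#'   r-squared of the retained panel, in `(0, 1]`.
#' @param window,step window size and step (in markers) for the sliding scan.
#' @return A list with the pruned `geno` and a `report` tibble recording the
#'   pairwise cut used and the achieved mean adjacent r-squared.
#' @export
ld_prune <- function(parents, target_mean_r2 = 0.9, window = 50, step = 25) {
  stopifnot(target_mean_r2 > 0, target_mean_r2 <= 1)
  n_in <- ncol(parents$dosage)
  # exact duplicates (r2 = 1) are redundant at any target and always dropped
  cut_max <- 0.9995
  keep0 <- prune_at_cut(parents, cut_max, window, step)
  g0 <- geno_subset(parents, markers = which(keep0))
  m0 <- mean_adjacent_r2(g0)
  if (is.na(m0) || m0 <= target_mean_r2) {
    rep0 <- qc_report_row("ld_prune", n_in, sum(keep0),
                          "duplicate removal only")
    rep0$cut <- cut_max; rep0$mean_adj_r2 <- m0
    return(list(geno = g0, report = rep0))
  }
  lo <- 0; hi <- cut_max
  best_keep <- keep0; best_cut <- cut_max
  for (it in 1:12) {
    cut <- (lo + hi) / 2
    keep <- prune_at_cut(parents, cut, window, step)
    ach <- mean_adjacent_r2(geno_subset(parents, markers = which(keep)))
    if (is.na(ach) || ach <= target_mean_r2) {
      best_keep <- keep; best_cut <- cut
      lo <- cut                     # try a milder cut
    } else {
      hi <- cut
    }
  }
  out <- geno_subset(parents, markers = which(best_keep))
  rep1 <- qc_report_row("ld_prune", n_in, sum(best_keep),
                        sprintf("target=%g", target_mean_r2))
  rep1$cut <- best_cut
  rep1$mean_adj_r2 <- mean_adjacent_r2(out)
  list(geno = out, report = rep1)
}

#' Build in-silico single-cross genotypes from homozygous parents
#'
#' Because the parents are fully homozygous, each hybrid genotype is
#' deterministic: its dosage is the mean of the two parental dosages, giving
#' 0, 1 or 2 with 1 wherever the parents carry different alleles.
#'
#' @param parents a [geno] object, homozygous and complete.
#' @param design a diallel design tibble (`hybrid_id`, `parent1`, `parent2`).
#' @return A [geno] object with `role = "hybrids"`.
#' @export
make_hybrid_genotypes <- function(parents, design) {
  d <- parents$dosage
  if (anyNA(d)) stop("parents contain missing data; impute first")
  if (any(d == 1)) stop("parents must be fully homozygous")
  unknown <- setdiff(unique(c(design$parent1, design$parent2)), rownames(d))
  if (length(unknown)) {
    stop("design references unknown parent(s): ",
         paste(unknown, collapse = ", "))
  }
  hyb <- (d[design$parent1, , drop = FALSE] +
            d[design$parent2, , drop = FALSE]) / 2
  rownames(hyb) <- design$hybrid_id
  geno(hyb, parents$map, role = "hybrids")
}

#' Minor allele frequency filter
#'
#' @param g a [geno] object with complete data.
#' @param min_maf minimum minor allele frequency.
#' @return A list with the filtered `geno` and a `report` tibble.
#' @export
maf_filter <- function(g, min_maf = 0.05) {
  if (anyNA(g$dosage)) stop("maf_filter() requires complete data")
  p <- colMeans(g$dosage) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= min_maf
  list(geno = geno_subset(g, markers = which(keep)),
       report = qc_report_row("maf_filter", length(keep), sum(keep),
                              sprintf("min_maf=%g", min_maf)))
}

#' Hardy-Weinberg equilibrium chi-square test per marker
#'
#' One-degree-of-freedom goodness-of-fit of the observed genotype counts to
#' the p-squared / 2pq / q-squared expectations at the sample allele
#' frequency.
#'
#' @param g a [geno] object with complete data.
#' @return A tibble (`marker_id`, `chisq`, `p_hwe`) with attribute
#'   `small_sample` flagging fewer than 5 samples.
#' @export
hwe_test <- function(g) {
  d <- g$dosage
  if (anyNA(d)) stop("hwe_test() requires complete data")
  n <- nrow(d)
  n2 <- colSums(d == 2); n1 <- colSums(d == 1); n0 <- colSums(d == 0)
  p <- (2 * n2 + n1) / (2 * n)
  q <- 1 - p
  e2 <- n * p^2; e1 <- n * 2 * p * q; e0 <- n * q^2
  chisq <- ifelse(p %in% c(0, 1), 0,
                  (n2 - e2)^2 / e2 + (n1 - e1)^2 / e1 + (n0 - e0)^2 / e0)
  out <- tibble::tibble(marker_id = colnames(d), chisq = chisq,
                        p_hwe = stats::pchisq(chisq, df = 1,
                                              lower.tail = FALSE))
  if (n < 5) {
    warning("fewer than 5 samples; HWE chi-square is unreliable")
    attr(out, "small_sample") <- TRUE
  } else {
    attr(out, "small_sample") <- FALSE
  }
  out
}

#' Run the full marker QC pipeline
#'
#' Call-rate filter, heterozygote drop, homozygous imputation and LD pruning
#' on the parents, then in-silico hybrid construction and a MAF filter on
#' the hybrids.
#'
#' @param parents a [geno] object of parents.
#' @param design a diallel design tibble.
#' @param min_call_rate,min_maf,target_mean_r2 stage thresholds.
#' @param window,step LD-pruning window parameters.
#' @param seed seed for the imputation draws.
#' @return A list with `parents` (QC'd), `hybrids`, and the stacked
#'   `report` tibble.
#' @export
qc_pipeline <- function(parents, design, min_call_rate = 0.95,
                        min_maf = 0.05, target_mean_r2 = 0.9,
                        window = 50, step = 25, seed = 1L) {
  s1 <- filter_call_rate(parents, min_call_rate)
  s2 <- drop_het_markers(s1$geno)
  g3 <- impute_homozygous(s2$geno, seed = seed)
  s4 <- ld_prune(g3, target_mean_r2, window, step)
  hyb <- make_hybrid_genotypes(s4$geno, design)
  s6 <- maf_filter(hyb, min_maf)
  list(
    parents = geno_subset(s4$geno, markers = colnames(s6$geno$dosage)),
    hybrids = s6$geno,
    report = dplyr::bind_rows(s1$report, s2$report, s4$report, s6$report)
  )
}
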