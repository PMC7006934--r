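new_kinship <- function(mat, kind, markers = NULL) {
  stopifnot(isSymmetric(unname(mat), tol = 1e-10))
  structure(mat, kind = kind, markers = markers, class = c("kinship", "matrix"))
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("<kinship '%s': %d x %d, trace %.3f>\n",
              attr(x, "kind"), nrow(x), ncol(x), sum(diag(x))))
  invisible(x)
}

dosage_of <- function(g) if (inherits(g, "geno")) g$dosage else as.matrix(g)

#' Trace-normalised genomic relationship matrix
#'
#' G = ZZ' * n / trace(ZZ') with Z the \{-1,0,1\}-coded dosages (no
#' frequency centering), so that trace(G) = n. Used with all markers this is
#' the kernel for GBLUP; restricted to the non-significant marker set it is
#' the kernel of the MAS-augmented models.
#'
#' @param g a [geno] object or dosage matrix with no missing values.
#' @param markers optional marker ids or indices to restrict to.
#' @param center if `TRUE`, columns are centered at twice the allele
#'   frequency before the cross-product (off by default: the trace-normalised
#'   kernel is defined on the raw coding).
#' @return A `kinship` matrix of kind `"trace_norm"`.
#' @export
grm_trace_norm <- function(g, markers = NULL, center = FALSE) {
  d <- dosage_of(g)
  if (!is.null(markers)) d <- d[, markers, drop = FALSE]
  if (ncol(d) == 0) stop("empty marker subset")
  if (anyNA(d)) stop("missing dosages not allowed")
  Z <- d - 1
  if (center) Z <- sweep(Z, 2, colMeans(Z))
  G <- tcrossprod(Z)
  tr <- sum(diag(G))
  if (tr == 0) stop("all markers monomorphic; trace is zero")
  G <- G * nrow(d) / tr
  dimnames(G) <- list(rownames(d), rownames(d))
  new_kinship(G, "trace_norm", markers = colnames(d))
}

#' VanRaden additive genomic relationship matrix
#'
#' Columns of the dosage matrix are centered at twice the allele frequency
#' and the cross-product is scaled by 2 * sum(p_j (1 - p_j)). Frequencies
#' are always computed on the sample set the matrix is built from.
#'
#' @inheritParams grm_trace_norm
#' @return A `kinship` matrix of kind `"vanraden_A"`.
#' @export
grm_additive <- function(g, markers = NULL) {
  d <- dosage_of(g)
  if (!is.null(markers)) d <- d[, markers, drop = FALSE]
  if (anyNA(d)) stop("missing dosages not allowed")
  p <- colMeans(d) / 2
  mono <- p %in% c(0, 1)
  if (any(mono)) {
    warning(sum(mono), " monomorphic marker(s) excluded from the additive GRM")
    d <- d[, !mono, drop = FALSE]; p <- p[!mono]
  }
  if (ncol(d) == 0) stop("no polymorphic markers left")
  Z <- sweep(d, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(d), rownames(d))
  new_kinship(G, "vanraden_A", markers = colnames(d))
}

#' Dominance genomic relationship matrix
#'
#' Heterozygote-indicator columns centered at 2 p_j q_j, scaled by
#' sum(2 p_j q_j (1 - p_j q_j)).
#'
#' @inheritParams grm_trace_norm
#' @return A `kinship` matrix of kind `"dominance_D"`.
#' @export
grm_dominance <- function(g, markers = NULL) {
  d <- dosage_of(g)
  if (!is.null(markers)) d <- d[, markers, drop = FALSE]
  if (anyNA(d)) stop("missing dosages not allowed")
  p <- colMeans(d) / 2
  mono <- p %in% c(0, 1)
  if (any(mono)) {
    warning(sum(mono), " monomorphic marker(s) excluded from the dominance GRM")
    d <- d[, !mono, drop = FALSE]; p <- p[!mono]
  }
  if (ncol(d) == 0) stop("no polymorphic markers left")
  q <- 1 - p
  W <- sweep((d == 1) * 1, 2, 2 * p * q)
  G <- tcrossprod(W) / sum(2 * p * q * (1 - p * q))
  dimnames(G) <- list(rownames(d), rownames(d))
  new_kinship(G, "dominance_D", markers = colnames(d))
}

#' Gaussian kernel from a genomic relationship matrix
#'
#' Squared genomic distances d_ij = G_ii + G_jj - 2 G_ij are scaled by their
#' median off-diagonal value and mapped through K_ij = exp(-h d_ij / median),
#' giving a unit-diagonal kernel with entries in (0, 1].
#'
#' @param G a `kinship` (or plain symmetric) matrix.
#' @param h bandwidth, > 0; larger h decays faster with genomic distance.
#' @return A `kinship` matrix of kind `"gaussian_K"`.
#' @export
gaussian_kernel <- function(G, h = 1) {
  if (h <= 0) stop("bandwidth h must be > 0")
  G <- unclass(G)
  dd <- outer(diag(G), diag(G), "+") - 2 * G
  dd[dd < 0] <- 0                     # numerical guard
  med <- stats::median(dd[upper.tri(dd)])
  if (!is.finite(med) || med == 0) med <- 1
  K <- exp(-h * dd / med)
  dimnames(K) <- dimnames(G)
  new_kinship(K, "gaussian_K")
}

#' Principal-component covariates for population structure
#'
#' Leading principal components of the column-centered dosage matrix, with a
#' deterministic sign convention (the largest-magnitude loading of each
#' component is positive).
#'
#' @param g a [geno] object or dosage matrix, complete.
#' @param n_pc number of components, from 0 to n - 1.
#' @return An n x n_pc matrix of scores (zero columns when `n_pc = 0`).
#' @export
pca_covariates <- function(g, n_pc) {
  d <- dosage_of(g)
  if (anyNA(d)) stop("missing dosages not allowed")
  n <- nrow(d)
  if (n_pc > n - 1) stop("n_pc must be at most n - 1")
  if (n_pc == 0) {
    return(matrix(numeric(0), nrow = n, ncol = 0,
                  dimnames = list(rownames(d), NULL)))
  }
  X <- sweep(d, 2, colMeans(d))
  sv <- svd(X, nu = n_pc, nv = n_pc)
  flip <- vapply(seq_len(n_pc), function(k) {
    v <- sv$v[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(n_pc), drop = FALSE] %*%
                    diag(sv$d[seq_len(n_pc)], n_pc), 2, flip, "*")
  dimnames(scores) <- list(rownames(d), paste0("PC", seq_len(n_pc)))
  scores
}
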