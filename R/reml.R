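# Restricted maximum likelihood for kernel mixed models
#
# y = X beta + u + e,  u ~ N(0, sigma2_g * G),  e ~ N(0, sigma2_e * I).
# The single-kernel solver profiles the restricted likelihood over
# delta = sigma2_e / sigma2_g on the spectrum of the projected kernel
# (the EMMA trick); the multi-kernel solver optimises the variance ratios
# numerically with Cholesky solves.

reml_single_kernel <- function(y, X, G, lower = 1e-6, upper = 1e6) {
  n <- length(y)
  qrX <- qr(X)
  q <- qrX$rank
  # rotate into the orthogonal complement of the fixed-effect space; the
  # restricted likelihood lives entirely in A'y ~ N(0, sigma2_g (A'GA + dI))
  A <- qr.Q(qrX, complete = TRUE)[, (q + 1):n, drop = FALSE]
  es <- eigen(crossprod(A, G %*% A), symmetric = TRUE)
  xi <- pmax(es$values, 0)
  eta2 <- drop(crossprod(es$vectors, crossprod(A, y)))^2

  ll <- function(log_delta) {
    d <- exp(log_delta)
    s <- eta2 / (xi + d)
    0.5 * ((n - q) * (log((n - q) / (2 * pi)) - 1 - log(sum(s))) -
             sum(log(xi + d)))
  }
  grid <- seq(log(lower), log(upper), length.out = 40)
  vals <- vapply(grid, ll, numeric(1))
  k <- which.max(vals)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  sigma2_g <- sum(eta2 / (xi + delta)) / (n - q)
  sigma2_e <- delta * sigma2_g
  list(delta = delta, sigma2_g = sigma2_g, sigma2_e = sigma2_e,
       logl = opt$objective)
}

# Generalised least squares + BLUP given variance components.
# G_full covers all samples (rows/cols); obs indexes the phenotyped ones.
kernel_blup <- function(y_obs, X_obs, G_full, obs, delta) {
  Go <- G_full[obs, obs, drop = FALSE]
  eg <- eigen((Go + t(Go)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  Hi <- eg$vectors %*% (t(eg$vectors) / (d + delta))
  XtHiX <- crossprod(X_obs, Hi %*% X_obs)
  beta <- solve(XtHiX, crossprod(X_obs, Hi %*% y_obs))
  resid <- y_obs - X_obs %*% beta
  u_all <- drop(G_full[, obs, drop = FALSE] %*% (Hi %*% resid))
  list(beta = drop(beta), u = u_all)
}

reml_multi_kernel <- function(y, X, kernels, max_iter = 200) {
  n <- length(y)
  q <- qr(X)$rank
  nk <- length(kernels)
  neg_llr <- function(log_theta) {
    th <- exp(log_theta)
    V <- diag(n)
    for (k in seq_len(nk)) V <- V + th[k] * kernels[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    XtViX <- crossprod(X, Vi_X)
    beta <- solve(XtViX, crossprod(X, Vi_y))
    Py <- Vi_y - Vi_X %*% beta
    s2 <- drop(crossprod(y, Py)) / (n - q)
    if (s2 <= 0) return(1e10)
    0.5 * ((n - q) * log(s2) + 2 * sum(log(diag(ch))) +
             determinant(XtViX, logarithm = TRUE)$modulus + (n - q))
  }
  opt <- stats::optim(rep(log(0.5), nk), neg_llr, method = "Nelder-Mead",
                      control = list(maxit = max_iter * 10, reltol = 1e-10))
  th <- exp(opt$par)
  V <- diag(n)
  for (k in seq_len(nk)) V <- V + th[k] * kernels[[k]]
  ch <- chol(V)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  beta <- solve(crossprod(X, Vi_X), crossprod(X, Vi_y))
  Py <- Vi_y - Vi_X %*% beta
  sigma2_e <- drop(crossprod(y, Py)) / (n - q)
  list(theta = th, sigma2_e = sigma2_e,
       sigma2_k = th * sigma2_e, logl = -opt$value,
       converged = opt$convergence == 0)
}
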