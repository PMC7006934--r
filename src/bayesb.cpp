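#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the BayesB marker-effect model:
//   y = mu + Z b + e,   b_j = 0 with probability pi,
//   b_j ~ N(0, sigma2_bj) otherwise, sigma2_bj ~ scaled-inv-chisq(df_b, S_b),
//   pi ~ Beta(pi_a, pi_b) (or fixed when pi_fixed >= 0),
//   e ~ N(0, sigma2_e), sigma2_e ~ scaled-inv-chisq(df_e, S_e).
// Uses R's RNG, so set.seed() on the R side makes chains reproducible.
// [[Rcpp::export]]
List bayesb_gibbs(NumericVector y, NumericMatrix Z,
                  int n_iter, int burn_in, int thin,
                  double df_b, double S_b, double df_e, double S_e,
                  double pi_a, double pi_b, double pi_fixed) {
  int n = y.size(), m = Z.ncol();
  std::vector<double> b(m, 0.0), s2b(m, S_b), zz(m);
  std::vector<double> e(n);
  double mu = mean(y);
  double pi = (pi_fixed >= 0) ? pi_fixed : 0.5;
  double s2e = S_e;

  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    zz[j] = s;
  }
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  std::vector<double> b_sum(m, 0.0), d_sum(m, 0.0);
  double mu_sum = 0.0, s2e_sum = 0.0, pi_sum = 0.0;
  int nkeep = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // intercept
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = mu + ebar + norm_rand() * std::sqrt(s2e / n);
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    int n_in = 0;
    for (int j = 0; j < m; ++j) {
      if (zz[j] <= 0) { b[j] = 0.0; continue; }
      // rhs with the current effect added back
      double r = zz[j] * b[j];
      for (int i = 0; i < n; ++i) r += Z(i, j) * e[i];
      double v1 = zz[j] * zz[j] * s2b[j] + zz[j] * s2e; // var(r | in)
      double v0 = zz[j] * s2e;                          // var(r | out)
      double log_lr = 0.5 * (std::log(v0) - std::log(v1)) +
                      0.5 * r * r * (1.0 / v0 - 1.0 / v1);
      double log_odds = std::log(1.0 - pi) - std::log(pi) + log_lr;
      double p_in = 1.0 / (1.0 + std::exp(-log_odds));
      double b_new;
      bool incl = unif_rand() < p_in;
      if (incl) {
        double C = zz[j] + s2e / s2b[j];
        b_new = r / C + norm_rand() * std::sqrt(s2e / C);
        ++n_in;
      } else {
        b_new = 0.0;
      }
      double db = b_new - b[j];
      if (db != 0.0) for (int i = 0; i < n; ++i) e[i] -= Z(i, j) * db;
      b[j] = b_new;
      // marker variance: posterior update when in, prior draw when out
      if (incl) {
        s2b[j] = (b[j] * b[j] + df_b * S_b) / Rf_rchisq(df_b + 1.0);
      } else {
        s2b[j] = df_b * S_b / Rf_rchisq(df_b);
      }
      if (it > burn_in && (it - burn_in) % thin == 0) d_sum[j] += incl;
    }

    if (pi_fixed < 0) {
      pi = Rf_rbeta(pi_a + (m - n_in), pi_b + n_in);
      pi = std::min(std::max(pi, 1e-8), 1.0 - 1e-8);
    }

    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = (sse + df_e * S_e) / Rf_rchisq(df_e + n);
    if (!R_finite(s2e) || s2e <= 0.0)
      stop("residual variance diverged at iteration %d", it);

    if (it > burn_in && (it - burn_in) % thin == 0) {
      ++nkeep;
      for (int j = 0; j < m; ++j) b_sum[j] += b[j];
      mu_sum += mu; s2e_sum += s2e; pi_sum += pi;
    }
  }

  NumericVector b_hat(m), d_hat(m);
  for (int j = 0; j < m; ++j) {
    b_hat[j] = b_sum[j] / nkeep;
    d_hat[j] = d_sum[j] / nkeep;
  }
  return List::create(_["b"] = b_hat, _["d"] = d_hat,
                      _["mu"] = mu_sum / nkeep,
                      _["sigma2_e"] = s2e_sum / nkeep,
                      _["pi"] = pi_sum / nkeep);
}
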