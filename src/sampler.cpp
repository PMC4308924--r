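#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return 0.0;
  return std::log1p(std::exp(x));
}

// Adaptive random-walk Metropolis within Gibbs for the Bernoulli-logistic
// model with ridge (normal) priors on fixed-effect columns and a shared
// variance, itself inverse-gamma distributed, on domain-effect columns.
// Columns of X are updated one at a time; the domain variance has a
// conjugate inverse-gamma full conditional and is drawn exactly. Proposal
// scales adapt towards a 0.44 acceptance rate during burn-in only, keeping
// the post burn-in kernel fixed. Uses R's RNG: seeding is done from R.
//
// Returns draws as a (kept * n_chains) x (P + 1) matrix; the last column is
// the domain variance (constant 1 when there are no domain columns).
// [[Rcpp::export]]
List pp_mcmc_cpp(NumericMatrix X, IntegerVector y, LogicalVector is_domain,
                 double prior_var, double ig_shape, double ig_rate,
                 int n_chains, int n_iter, double burn_fraction) {
  const int n = X.nrow(), P = X.ncol();
  const int n_burn = (int)std::floor(burn_fraction * n_iter);
  const int kept = n_iter - n_burn;
  if (kept < 1) stop("burn fraction leaves no kept iterations");

  // non-zero entries per column (class-specific columns are sparse)
  std::vector<std::vector<int> > nz(P);
  for (int j = 0; j < P; ++j)
    for (int i = 0; i < n; ++i)
      if (X(i, j) != 0.0) nz[j].push_back(i);

  int n_dom = 0;
  for (int j = 0; j < P; ++j) if (is_domain[j]) ++n_dom;

  NumericMatrix draws(kept * n_chains, P + 1);
  NumericMatrix accept(n_chains, P);

  for (int c = 0; c < n_chains; ++c) {
    std::vector<double> theta(P, 0.0), eta(n, 0.0), sd(P, 0.5);
    std::vector<int> acc_win(P, 0);
    double sigma2 = 1.0;

    for (int t = 0; t < n_iter; ++t) {
      for (int j = 0; j < P; ++j) {
        double prop = theta[j] + sd[j] * norm_rand();
        double diff = prop - theta[j];
        double dll = 0.0;
        const std::vector<int>& rows = nz[j];
        for (size_t k = 0; k < rows.size(); ++k) {
          int i = rows[k];
          double e_new = eta[i] + X(i, j) * diff;
          dll += y[i] * (e_new - eta[i]) - softplus(e_new) + softplus(eta[i]);
        }
        double pv = is_domain[j] ? sigma2 : prior_var;
        double dlp = -(prop * prop - theta[j] * theta[j]) / (2.0 * pv);
        if (std::log(unif_rand()) < dll + dlp) {
          for (size_t k = 0; k < rows.size(); ++k)
            eta[rows[k]] += X(rows[k], j) * diff;
          theta[j] = prop;
          acc_win[j]++;
          accept(c, j) += 1.0;
        }
      }
      // adapt proposal scales during burn-in
      if (t < n_burn && (t + 1) % 50 == 0) {
        for (int j = 0; j < P; ++j) {
          double rate = acc_win[j] / 50.0;
          sd[j] *= std::exp(rate > 0.44 ? 0.1 : -0.1);
          acc_win[j] = 0;
        }
      }
      // conjugate draw for the domain-effect variance
      if (n_dom > 0) {
        double ssq = 0.0;
        for (int j = 0; j < P; ++j)
          if (is_domain[j]) ssq += theta[j] * theta[j];
        double shape = ig_shape + 0.5 * n_dom;
        double rate = ig_rate + 0.5 * ssq;
        sigma2 = 1.0 / R::rgamma(shape, 1.0 / rate);
      }
      if (t >= n_burn) {
        int row = c * kept + (t - n_burn);
        for (int j = 0; j < P; ++j) draws(row, j) = theta[j];
        draws(row, P) = sigma2;
      }
    }
    for (int j = 0; j < P; ++j) accept(c, j) /= n_iter;
  }

  return List::create(_["draws"] = draws, _["accept"] = accept,
                      _["kept"] = kept);
}
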