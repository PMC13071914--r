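#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Single-site Metropolis sampler for the semi-grand protonation model.
// One frame = one full sweep over sites in fixed order; at each site a flip
// is attempted with its per-site attempt probability (emulating slow proton
// exchangers) and accepted with min(1, exp(-dE/kT)). All randomness comes
// from R's RNG stream, so set.seed() upstream gives bit-identical output.
//
// mu[i] = ln(10)*kT*(pH - pKa_i); W = pairwise coupling (kcal/mol).
// dE for flipping site i: (1 - 2 s_i) * (mu_i + sum_j W_ij s_j).

// [[Rcpp::export(name = ".cpp_metropolis")]]
IntegerMatrix cpp_metropolis(NumericVector mu, NumericMatrix W,
                             NumericVector attempt_prob, double kT,
                             IntegerVector init, int n_frames,
                             int n_burnin) {
  const int n = mu.size();
  // sparse neighbour lists
  std::vector<std::vector<int> > nb(n);
  std::vector<std::vector<double> > wnb(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i != j && W(i, j) != 0.0) {
        nb[i].push_back(j);
        wnb[i].push_back(W(i, j));
      }
    }
  }
  std::vector<int> s(init.begin(), init.end());
  IntegerMatrix out(n_frames, n);
  const int total = n_burnin + n_frames;
  for (int t = 0; t < total; ++t) {
    for (int i = 0; i < n; ++i) {
      const double a = attempt_prob[i];
      if (a < 1.0 && unif_rand() >= a) continue;
      double field = mu[i];
      const std::vector<int>& nbi = nb[i];
      const std::vector<double>& wi = wnb[i];
      for (size_t k = 0; k < nbi.size(); ++k) field += wi[k] * s[nbi[k]];
      const double dE = (1 - 2 * s[i]) * field;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE / kT)) s[i] = 1 - s[i];
    }
    if (t >= n_burnin) {
      const int row = t - n_burnin;
      for (int i = 0; i < n; ++i) out(row, i) = s[i];
    }
  }
  return out;
}
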