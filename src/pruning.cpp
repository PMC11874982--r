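// Two-state (absent/present) pruning likelihood over all gene families and
// gamma rate categories. Postorder edge traversal with per-family rescaling;
// stationary root frequencies. This is the hot loop of the gain/loss model
// fit; the inside-outside pass used for per-branch expectations stays in R.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// edge: 2-column (parent, child) matrix in postorder, 1-based node ids with
// tips 1..n_tip. X: n_tip x n_fam 0/1 tip states (row i = node id i).
// Returns n_fam x K matrix of per-family log-likelihoods, one column per
// rate multiplier in `rates` (each scales gain and loss jointly).
// [[Rcpp::export]]
NumericMatrix pruning_loglik_cpp(IntegerMatrix edge, NumericVector edge_length,
                                 int n_tip, int n_node,
                                 IntegerMatrix X, double g, double l,
                                 NumericVector rates) {
  const int n_fam = X.ncol();
  const int n_edge = edge.nrow();
  const int K = rates.size();
  NumericMatrix out(n_fam, K);
  std::vector<double> D0((size_t)n_node * n_fam);
  std::vector<double> D1((size_t)n_node * n_fam);
  std::vector<double> logscale(n_fam);

  int root = edge(n_edge - 1, 0) - 1;  // last postorder edge leaves the root

  for (int k = 0; k < K; ++k) {
    const double gk = g * rates[k], lk = l * rates[k];
    const double s = gk + lk;
    const double pi1 = (s > 0) ? gk / s : 0.0;
    std::fill(D0.begin(), D0.end(), 1.0);
    std::fill(D1.begin(), D1.end(), 1.0);
    std::fill(logscale.begin(), logscale.end(), 0.0);
    for (int i = 0; i < n_tip; ++i) {
      double *d0 = &D0[(size_t)i * n_fam], *d1 = &D1[(size_t)i * n_fam];
      for (int f = 0; f < n_fam; ++f) {
        const int x = X(i, f);
        d0[f] = 1 - x;
        d1[f] = x;
      }
    }
    for (int e = 0; e < n_edge; ++e) {
      const int par = edge(e, 0) - 1, chd = edge(e, 1) - 1;
      const double t = edge_length[e];
      const double em = (s > 0) ? std::exp(-s * t) : 1.0;
      const double p01 = pi1 * (1 - em), p10 = (1 - pi1) * (1 - em);
      const double p00 = 1 - p01, p11 = 1 - p10;
      double *c0 = &D0[(size_t)chd * n_fam], *c1 = &D1[(size_t)chd * n_fam];
      double *u0 = &D0[(size_t)par * n_fam], *u1 = &D1[(size_t)par * n_fam];
      if (chd >= n_tip) {  // internal child now complete: rescale
        for (int f = 0; f < n_fam; ++f) {
          double sc = c0[f] > c1[f] ? c0[f] : c1[f];
          if (sc <= 0) sc = 1.0;
          c0[f] /= sc;
          c1[f] /= sc;
          logscale[f] += std::log(sc);
        }
      }
      for (int f = 0; f < n_fam; ++f) {
        u0[f] *= p00 * c0[f] + p01 * c1[f];
        u1[f] *= p10 * c0[f] + p11 * c1[f];
      }
    }
    const double pi0 = 1 - pi1;
    double *r0 = &D0[(size_t)root * n_fam], *r1 = &D1[(size_t)root * n_fam];
    for (int f = 0; f < n_fam; ++f)
      out(f, k) = std::log(pi0 * r0[f] + pi1 * r1[f]) + logscale[f];
  }
  return out;
}
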