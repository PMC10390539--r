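#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for the Li-Stephens haplotype-copying HMM.
//
// Hidden state = which of the K panel haplotypes the target copies.
// Transition between adjacent sites (distance d): stay with 1 - s + s/K,
// switch to each other state with s/K, where s = 1 - exp(-rho * d / K).
// Emission at typed sites: 1 - err on allele match, err on mismatch;
// untyped sites emit uniformly (all states weight 1).
//
// panel:   K x M 0/1 matrix
// pos:     M physical positions (for inter-site distances)
// typed:   0-based indices of typed sites (strictly increasing)
// obs:     observed target alleles at typed sites (0/1)
// Returns gamma (M x K posterior matrix, rows sum to 1).
// [[Rcpp::export(name = ".ls_fb_cpp")]]
NumericMatrix ls_fb_cpp(const IntegerMatrix& panel, const NumericVector& pos,
                        const IntegerVector& typed, const IntegerVector& obs,
                        double rho, double err) {
  const int K = panel.nrow(), M = panel.ncol(), T = typed.size();
  NumericMatrix alpha(M, K), gamma(M, K);
  std::vector<double> sw(M, 0.0);          // switch prob into site m
  std::vector<int> typed_at(M, -1);        // observed allele at site, -1 untyped
  for (int t = 0; t < T; ++t) typed_at[typed[t]] = obs[t];
  for (int m = 1; m < M; ++m) {
    double d = pos[m] - pos[m - 1];
    if (d < 1.0) d = 1.0;
    sw[m] = 1.0 - std::exp(-rho * d / K);
  }

  // forward, rescaled to sum 1 per site
  double tot = 0.0;
  for (int k = 0; k < K; ++k) {
    double e = 1.0;
    if (typed_at[0] >= 0) e = (panel(k, 0) == typed_at[0]) ? 1.0 - err : err;
    alpha(0, k) = e / K;
    tot += alpha(0, k);
  }
  for (int k = 0; k < K; ++k) alpha(0, k) /= tot;
  for (int m = 1; m < M; ++m) {
    const double s = sw[m];
    tot = 0.0;
    for (int k = 0; k < K; ++k) {
      double pred = (1.0 - s) * alpha(m - 1, k) + s / K;  // sum(alpha) == 1
      double e = 1.0;
      if (typed_at[m] >= 0) e = (panel(k, m) == typed_at[m]) ? 1.0 - err : err;
      alpha(m, k) = e * pred;
      tot += alpha(m, k);
    }
    for (int k = 0; k < K; ++k) alpha(m, k) /= tot;
  }

  // backward (rescaled each step; gamma is normalized per site anyway)
  std::vector<double> beta(K, 1.0), tmp(K);
  tot = 0.0;
  for (int k = 0; k < K; ++k) { gamma(M - 1, k) = alpha(M - 1, k); tot += gamma(M - 1, k); }
  for (int k = 0; k < K; ++k) gamma(M - 1, k) /= tot;
  for (int m = M - 2; m >= 0; --m) {
    const double s = sw[m + 1];
    double tsum = 0.0;
    for (int k = 0; k < K; ++k) {
      double e = 1.0;
      if (typed_at[m + 1] >= 0)
        e = (panel(k, m + 1) == typed_at[m + 1]) ? 1.0 - err : err;
      tmp[k] = e * beta[k];
      tsum += tmp[k];
    }
    double bsum = 0.0;
    for (int k = 0; k < K; ++k) {
      beta[k] = (1.0 - s) * tmp[k] + (s / K) * tsum;
      bsum += beta[k];
    }
    tot = 0.0;
    for (int k = 0; k < K; ++k) {
      beta[k] /= bsum;
      gamma(m, k) = alpha(m, k) * beta[k];
      tot += gamma(m, k);
    }
    for (int k = 0; k < K; ++k) gamma(m, k) /= tot;
  }
  return gamma;
}
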