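#include <Rcpp.h>
using namespace Rcpp;

// EM for the binomial admixture likelihood
//   L = sum_im [ g log(sum_k q_ik f_km) + (2 - g) log(1 - sum_k q_ik f_km) ]
// with multiplicative updates from expected ancestry-of-allele counts.
// Missing genotypes (NA) contribute nothing. Returns the per-iteration
// log-likelihood trace; Q and F are updated in place.
// [[Rcpp::export(name = ".admixture_em_cpp")]]
List admixture_em_cpp(const IntegerMatrix& G, NumericMatrix Q, NumericMatrix F,
                      int max_iter, double tol) {
  const int n = G.nrow(), m = G.ncol(), K = Q.ncol();
  std::vector<double> trace;
  trace.reserve(max_iter);
  NumericMatrix Qn(n, K);
  NumericMatrix Fnum(K, m), Fden(K, m);
  std::vector<double> aik(K), bik(K);
  double ll_old = R_NegInf;
  bool converged = false;

  for (int it = 0; it < max_iter; ++it) {
    std::fill(Qn.begin(), Qn.end(), 0.0);
    std::fill(Fnum.begin(), Fnum.end(), 0.0);
    std::fill(Fden.begin(), Fden.end(), 0.0);
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < m; ++j) {
        const int g = G(i, j);
        if (g == NA_INTEGER) continue;
        double p = 0.0;
        for (int k = 0; k < K; ++k) p += Q(i, k) * F(k, j);
        if (p < 1e-9) p = 1e-9;
        if (p > 1.0 - 1e-9) p = 1.0 - 1e-9;
        ll += g * std::log(p) + (2 - g) * std::log(1.0 - p);
        for (int k = 0; k < K; ++k) {
          const double a = g * Q(i, k) * F(k, j) / p;
          const double b = (2 - g) * Q(i, k) * (1.0 - F(k, j)) / (1.0 - p);
          Qn(i, k) += a + b;
          Fnum(k, j) += a;
          Fden(k, j) += a + b;
        }
      }
    }
    trace.push_back(ll);
    if (R_finite(ll_old) && ll - ll_old < tol) { converged = true; break; }
    ll_old = ll;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += Qn(i, k);
      if (s < 1e-12) s = 1e-12;
      for (int k = 0; k < K; ++k) Q(i, k) = Qn(i, k) / s;
    }
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < m; ++j) {
        double f = Fnum(k, j) / std::max(Fden(k, j), 1e-12);
        if (f < 1e-6) f = 1e-6;
        if (f > 1.0 - 1e-6) f = 1.0 - 1e-6;
        F(k, j) = f;
      }
  }
  return List::create(_["Q"] = Q, _["F"] = F,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["converged"] = converged);
}
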