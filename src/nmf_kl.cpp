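// Multiplicative-update NMF minimizing the generalized Kullback-Leibler
// divergence D(V || WH) = sum( V log(V/WH) - V + WH ). Run inside the
// consensus/bootstrap loops, hence compiled. The divergence (whose log()
// terms dominate the per-iteration cost) is evaluated every checkInterval
// updates; convergence compares the per-iteration average change to tol.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double kl_div(const mat& V, const mat& WH) {
  double d = 0.0;
  const double* v = V.memptr();
  const double* w = WH.memptr();
  const uword n = V.n_elem;
  for (uword i = 0; i < n; ++i) {
    d += (v[i] > 0.0 ? v[i] * std::log(v[i] / w[i]) - v[i] : 0.0) + w[i];
  }
  return d;
}

static void clamp_floor(mat& X, double eps) {
  X.transform([eps](double x) { return x < eps ? eps : x; });
}

// [[Rcpp::export]]
Rcpp::List nmf_kl_cpp(const arma::mat& V, const arma::mat& W0,
                      const arma::mat& H0, int maxIter, double tol,
                      int checkInterval) {
  const double eps = 1e-12;
  if (checkInterval < 1) checkInterval = 1;
  mat W = W0, H = H0;
  mat WH = W * H;
  clamp_floor(WH, eps);
  std::vector<double> trace;
  trace.reserve(64);
  double prev = kl_div(V, WH);
  trace.push_back(prev);
  bool converged = false;
  int it = 0, sinceCheck = 0;
  while (it < maxIter) {
    ++it;
    ++sinceCheck;
    // H <- H .* (W' (V ./ WH)) ./ colSums(W)
    mat R = V / WH;
    vec wc = sum(W, 0).t() + eps;
    H %= (W.t() * R);
    H.each_col() /= wc;
    WH = W * H;
    clamp_floor(WH, eps);
    // W <- W .* ((V ./ WH) H') ./ rowSums(H)
    R = V / WH;
    rowvec hr = sum(H, 1).t() + eps;
    W %= (R * H.t());
    W.each_row() /= hr;
    WH = W * H;
    clamp_floor(WH, eps);
    if (sinceCheck == checkInterval || it == maxIter) {
      double cur = kl_div(V, WH);
      trace.push_back(cur);
      if (std::abs(prev - cur) / sinceCheck <=
          tol * std::max(std::abs(prev), eps)) {
        converged = true;
        break;
      }
      prev = cur;
      sinceCheck = 0;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("H") = H,
      Rcpp::Named("divergence") = trace.back(),
      Rcpp::Named("trace") = trace,
      Rcpp::Named("iterations") = it,
      Rcpp::Named("converged") = converged);
}
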