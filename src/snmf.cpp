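// Multiplicative-update NMF inner loop (Frobenius objective).
// Initial factors are drawn in R so that all randomness goes through R's RNG.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lee-Seung updates for min ||Y - WH||_F^2 with W,H >= 0.
// eps guards denominators; the objective is monotone non-increasing.
// [[Rcpp::export(name = ".nmf_mu_cpp")]]
Rcpp::List nmf_mu_cpp(const arma::mat& Y, arma::mat W, arma::mat H,
                      int max_iter, double tol, double eps) {
  const double ynorm2 = accu(square(Y));
  std::vector<double> trace;
  trace.reserve(max_iter);
  bool converged = false;
  double obj_prev = datum::inf;

  for (int it = 0; it < max_iter; ++it) {
    // H <- H .* (W'Y) ./ (W'W H + eps)
    mat WtY = W.t() * Y;
    mat WtWH = (W.t() * W) * H;
    H %= WtY / (WtWH + eps);

    // W <- W .* (Y H') ./ (W H H' + eps)
    mat YHt = Y * H.t();
    mat HHt = H * H.t();
    mat WHHt = W * HHt;
    W %= YHt / (WHHt + eps);

    // ||Y - WH||^2 = ||Y||^2 - 2<Y, WH> + ||WH||^2, via small Gram matrices
    mat HHt2 = H * H.t();
    double cross = accu((Y * H.t()) % W);
    double fit = accu((W.t() * W) % HHt2);
    double obj = ynorm2 - 2.0 * cross + fit;
    if (obj < 0) obj = 0; // numerical guard near exact fits
    trace.push_back(obj);

    if (std::isfinite(obj_prev)) {
      double rel = std::fabs(obj_prev - obj) / std::max(obj_prev, eps);
      if (rel < tol) { converged = true; break; }
    }
    obj_prev = obj;
  }

  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("objective_trace") = trace,
    Rcpp::Named("converged") = converged);
}
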