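#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Generalized KL divergence sum_ij( x log(x/y) - x + y ) with the
// 0*log(0/y) = 0 convention; y floored at eps inside the log only.
static double kld_sum(const mat& X, const mat& Y, double eps) {
  double s = 0.0;
  const uword n = X.n_elem;
  for (uword k = 0; k < n; ++k) {
    const double x = X(k);
    const double y = Y(k);
    if (x > 0.0) {
      const double yf = (y < eps) ? eps : y;
      s += x * std::log(x / yf) - x;
    }
    s += y;
  }
  return (s < 0.0) ? 0.0 : s;
}

// [[Rcpp::export(name = ".nmf_kl_fit_cpp")]]
Rcpp::List nmf_kl_fit_cpp(const arma::mat& X, arma::mat W, arma::mat H,
                          int max_iter, double tol, double eps,
                          int conv_window) {
  std::vector<double> trace;
  trace.reserve(max_iter + 1);

  mat WH = W * H;
  trace.push_back(kld_sum(X, WH, eps));

  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // H update: H_aj <- H_aj * [W' (X/WH)]_aj / colsum(W)_a
    mat R = X / clamp(WH, eps, datum::inf);
    mat numH = W.t() * R;
    vec ws = sum(W, 0).t();
    ws.transform([eps](double v) { return (v < eps) ? eps : v; });
    numH.each_col() /= ws;
    H %= numH;

    // W update: W_ia <- W_ia * [(X/WH) H']_ia / rowsum(H)_a
    WH = W * H;
    R = X / clamp(WH, eps, datum::inf);
    mat numW = R * H.t();
    rowvec hs = sum(H, 1).t();
    hs.transform([eps](double v) { return (v < eps) ? eps : v; });
    numW.each_row() /= hs;
    W %= numW;

    WH = W * H;
    const double loss = kld_sum(X, WH, eps);
    trace.push_back(loss);

    if (it >= conv_window) {
      const double prev = trace[it - conv_window];
      const double den = std::max(std::abs(prev), eps);
      if (std::abs(prev - loss) / den < tol) break;
    }
  }
  if (it > max_iter) it = max_iter;

  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("H") = H,
      Rcpp::Named("loss") = trace.back(),
      Rcpp::Named("n_iter") = it,
      Rcpp::Named("trace") = trace);
}

// [[Rcpp::export(name = ".kld_sum_cpp")]]
double kld_sum_export(const arma::mat& X, const arma::mat& Y, double eps) {
  return kld_sum(X, Y, eps);
}
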