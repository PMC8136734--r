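#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double kl_div(const mat& A, const mat& WH, double eps) {
  double D = 0.0;
  const uword nm = A.n_elem;
  for (uword t = 0; t < nm; ++t) {
    double a = A[t];
    double wh = WH[t] < eps ? eps : WH[t];
    D += (a > 0.0) ? a * std::log(a / wh) - a + wh : wh;
  }
  return D;
}

// Divergence-based multiplicative updates (H then W, sequential), with the
// generalized KL objective tracked every iteration.  eps clamps denominators
// and log arguments; tol is the relative decrease of D over `window`
// consecutive iterations below which the fit is declared converged.
// [[Rcpp::export]]
Rcpp::List nmf_kl_run(const arma::mat& A, arma::mat W, arma::mat H,
                      int max_iter, double tol, int window, double eps) {
  std::vector<double> trace;
  trace.reserve(64);
  bool converged = false;
  int iter = 0;
  mat WH = W * H;
  trace.push_back(kl_div(A, WH, eps));   // divergence at initialization

  while (iter < max_iter) {
    ++iter;
    // H_au <- H_au * sum_i W_ia A_iu / (WH)_iu / sum_k W_ka
    mat R = A / clamp(WH, eps, datum::inf);
    colvec wsum = sum(W, 0).t();          // k x 1 column sums of W
    H %= (W.t() * R);
    H.each_col() /= clamp(wsum, eps, datum::inf);
    WH = W * H;
    // W_ia <- W_ia * sum_u H_au A_iu / (WH)_iu / sum_v H_av
    R = A / clamp(WH, eps, datum::inf);
    rowvec hsum = sum(H, 1).t();          // 1 x k row sums of H
    W %= (R * H.t());
    W.each_row() /= clamp(hsum, eps, datum::inf);
    WH = W * H;

    double D = kl_div(A, WH, eps);
    if (!std::isfinite(D))
      Rcpp::stop("non-finite divergence at iteration %d (input scale problem)", iter);
    trace.push_back(D);
    int sz = (int) trace.size() - 1;       // completed update iterations
    if (sz > window) {
      double prev = trace[sz - window];
      double rel = (prev - D) / std::max(std::abs(prev), 1e-300);
      if (rel < tol) { converged = true; break; }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("divergence_trace") = trace,
    Rcpp::Named("n_iter") = iter,
    Rcpp::Named("converged") = converged);
}
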