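#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Multiplicative-update NMF for the Frobenius objective ||X - WH||_F
// (Lee & Seung). W and H are supplied already initialized so that all
// randomness stays under R's RNG. Convergence is declared when the
// relative change in reconstruction error over a 10-iteration window
// drops below tol.
// [[Rcpp::export(name = ".nmf_mu_cpp")]]
List nmf_mu_cpp(const arma::mat& X, arma::mat W, arma::mat H, int max_iter,
                double tol) {
  const double delta = 1e-12;
  double prev_err = arma::norm(X - W * H, "fro");
  int iters = 0;
  for (int it = 1; it <= max_iter; ++it) {
    H %= (W.t() * X) / (W.t() * W * H + delta);
    W %= (X * H.t()) / (W * H * H.t() + delta);
    iters = it;
    if (it % 10 == 0 || it == max_iter) {
      const double err = arma::norm(X - W * H, "fro");
      if (prev_err - err <= tol * std::max(prev_err, delta)) {
        prev_err = err;
        break;
      }
      prev_err = err;
    }
  }
  const double err = arma::norm(X - W * H, "fro");
  return List::create(_["W"] = W, _["H"] = H, _["recon_err"] = err,
                      _["iterations"] = iters);
}
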