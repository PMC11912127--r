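// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>

// Median of a small scratch vector (modifies its argument).
static double med_inplace(std::vector<double>& v) {
  const std::size_t n = v.size();
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

//' @name hampelDespikeMat
//' @keywords internal
// [[Rcpp::export(name = ".hampel_despike_mat")]]
Rcpp::NumericMatrix hampel_despike_mat(const Rcpp::NumericMatrix& Y,
                                       const int halfwidth,
                                       const double nsigma) {
  const int C = Y.nrow(), N = Y.ncol();
  if (C < 2) Rcpp::stop("spectra must have at least 2 channels");
  if (halfwidth < 1) Rcpp::stop("halfwidth must be >= 1");
  if (nsigma <= 0) Rcpp::stop("nsigma must be > 0");
  Rcpp::NumericMatrix out(Rcpp::clone(Y));
  std::vector<double> win, dev;
  win.reserve(2 * halfwidth + 1);
  dev.reserve(2 * halfwidth + 1);
  for (int j = 0; j < N; ++j) {
    for (int i = 0; i < C; ++i) {
      const int lo = std::max(0, i - halfwidth);
      const int hi = std::min(C - 1, i + halfwidth);
      win.assign(&Y(lo, j), &Y(hi, j) + 1);
      const double m = med_inplace(win);
      dev.resize(win.size());
      for (std::size_t k = 0; k < win.size(); ++k)
        dev[k] = std::abs(Y(lo + static_cast<int>(k), j) - m);
      // 1.4826 * MAD: consistent scale estimate for Gaussian noise
      const double sigma = 1.4826 * med_inplace(dev);
      if (std::abs(Y(i, j) - m) > nsigma * sigma) out(i, j) = m;
    }
  }
  return out;
}

//' @name modpolyBaselineMat
//' @keywords internal
// [[Rcpp::export(name = ".modpoly_baseline_mat")]]
arma::mat modpoly_baseline_mat(const arma::mat& Y, const arma::mat& Q,
                               const int iterations) {
  // Iterative modified polynomial fitting: repeatedly fit, then clip the
  // working spectrum to min(working, fit) so peaks are excluded from the fit.
  // Q holds an orthonormal polynomial basis (C x (order+1)), so each fit is
  // the orthogonal projection Q (Q' w).
  if (iterations < 1) Rcpp::stop("iterations must be >= 1");
  if (Q.n_rows != Y.n_rows) Rcpp::stop("basis/spectrum channel mismatch");
  arma::mat W = Y;
  arma::mat F;
  for (int it = 0; it < iterations; ++it) {
    F = Q * (Q.t() * W);
    // exact fixed point: if no element of the fit undercuts the working
    // spectrum, every remaining iteration reproduces this same fit
    if (!arma::any(arma::vectorise(F < W))) break;
    W = arma::min(W, F);
  }
  return F;  // final fitted baseline, one column per spectrum
}
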