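#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// varimax simplicity criterion of a loading matrix: sum over columns of the
// variance of squared loadings
static double vmx_criterion(const mat& Z) {
  mat Z2 = square(Z);
  rowvec m2 = mean(Z2, 0);
  rowvec m4 = mean(square(Z2), 0);
  return accu(m4 - square(m2));
}

// SVD-based varimax iteration on row-normalised loadings Z0; returns the
// orthogonal rotation matrix plus the per-iteration criterion trace
// [[Rcpp::export(name = ".varimax_engine")]]
Rcpp::List varimax_engine(const arma::mat& Z0, int max_iter, double tol) {
  const uword n = Z0.n_rows, k = Z0.n_cols;
  mat R = eye(k, k);
  double crit = vmx_criterion(Z0);
  std::vector<double> trace;
  trace.push_back(crit);
  bool converged = false;
  int it = 0;
  mat Z, B, U, V;
  vec s;
  while (it < max_iter) {
    ++it;
    Z = Z0 * R;
    B = Z0.t() * (pow(Z, 3) - Z * diagmat(sum(square(Z), 0) / double(n)));
    if (!svd(U, s, V, B)) Rcpp::stop("svd failure in varimax iteration");
    R = U * V.t();
    double newcrit = vmx_criterion(Z0 * R);
    trace.push_back(newcrit);
    if (newcrit - crit < tol * std::max(crit, datum::eps)) {
      crit = newcrit;
      converged = true;
      break;
    }
    crit = newcrit;
  }
  return Rcpp::List::create(
    Rcpp::Named("rotation") = R,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("criterion") = trace);
}
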