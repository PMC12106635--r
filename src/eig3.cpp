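#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Per-voxel eigen-decomposition of symmetric 3x3 Hessians supplied as six
// component vectors. Eigenvalues are returned sorted by |lambda| ascending
// (l1 = smallest magnitude); v1 is the unit eigenvector of l1, i.e. the
// candidate tube axis.
// [[Rcpp::export(name = ".eig3_sym")]]
List eig3_sym(NumericVector hxx, NumericVector hyy, NumericVector hzz,
              NumericVector hxy, NumericVector hxz, NumericVector hyz) {
  const R_xlen_t n = hxx.size();
  NumericVector l1(n), l2(n), l3(n), v1x(n), v1y(n), v1z(n);
  arma::mat33 A;
  arma::vec3 eval;
  arma::mat33 evec;
  for (R_xlen_t i = 0; i < n; ++i) {
    A(0, 0) = hxx[i]; A(1, 1) = hyy[i]; A(2, 2) = hzz[i];
    A(0, 1) = A(1, 0) = hxy[i];
    A(0, 2) = A(2, 0) = hxz[i];
    A(1, 2) = A(2, 1) = hyz[i];
    arma::eig_sym(eval, evec, A);
    // eig_sym sorts ascending by value; re-sort by absolute value
    arma::uvec ord = arma::sort_index(arma::abs(eval));
    l1[i] = eval(ord(0));
    l2[i] = eval(ord(1));
    l3[i] = eval(ord(2));
    v1x[i] = evec(0, ord(0));
    v1y[i] = evec(1, ord(0));
    v1z[i] = evec(2, ord(0));
  }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3,
                      _["v1x"] = v1x, _["v1y"] = v1y, _["v1z"] = v1z);
}
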