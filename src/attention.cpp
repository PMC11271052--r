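// Node-level dot-product graph attention kernels.
//
// Hot path of training: per head and per subgraph, score neighbours by
// the LeakyReLU of the projected-feature dot product, softmax-normalise
// over each node's neighbour set, aggregate through an ELU.  The
// backward pass is the exact reverse-mode gradient of the forward pass
// with respect to the projected features.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double leaky(double x, double slope) {
  return x > 0 ? x : slope * x;
}

// [[Rcpp::export(name = ".att_forward_cpp")]]
List att_forward_cpp(const arma::mat& A, const arma::mat& H, double slope) {
  const arma::uword n = A.n_rows;
  arma::mat S = H * H.t();
  arma::mat a(n, n);
  // masked, row-stabilised softmax of LeakyReLU(S) over each row's
  // neighbour set
  for (arma::uword i = 0; i < n; ++i) {
    double m = -arma::datum::inf;
    for (arma::uword j = 0; j < n; ++j) {
      if (A(i, j) != 0) {
        double v = leaky(S(i, j), slope);
        if (v > m) m = v;
      }
    }
    double tot = 0.0;
    for (arma::uword j = 0; j < n; ++j) {
      double e = 0.0;
      if (A(i, j) != 0) {
        e = std::exp(leaky(S(i, j), slope) - m);
        tot += e;
      }
      a(i, j) = e;
    }
    a.row(i) /= tot;
  }
  arma::mat P = a * H;
  arma::mat Z = P;
  for (arma::uword k = 0; k < Z.n_elem; ++k) {
    if (Z(k) < 0) Z(k) = std::expm1(Z(k));
  }
  return List::create(_["Z"] = Z, _["P"] = P, _["a"] = a, _["S"] = S);
}

// [[Rcpp::export(name = ".att_backward_cpp")]]
arma::mat att_backward_cpp(const arma::mat& A, const arma::mat& H,
                           double slope, const arma::mat& S,
                           const arma::mat& a, const arma::mat& P,
                           const arma::mat& Z, const arma::mat& dZ) {
  const arma::uword n = A.n_rows;
  // ELU'(x) = 1 for x > 0, exp(x) = Z + 1 otherwise
  arma::mat dP = dZ;
  for (arma::uword k = 0; k < dP.n_elem; ++k) {
    if (P(k) <= 0) dP(k) *= (Z(k) + 1.0);
  }
  arma::mat da = dP * H.t();
  arma::mat dH = a.t() * dP;
  // softmax backward per row, then LeakyReLU'
  arma::mat dS(n, n);
  for (arma::uword i = 0; i < n; ++i) {
    double s = arma::dot(a.row(i), da.row(i));
    for (arma::uword j = 0; j < n; ++j) {
      double g = a(i, j) * (da(i, j) - s);
      dS(i, j) = (S(i, j) > 0) ? g : slope * g;
    }
  }
  dH += (dS + dS.t()) * H;
  return dH;
}
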