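// Fused forward + reverse pass for the pi-net regression objective.
// This is the inner loop of MCMC sampling and Adam training, where the
// R-level implementation's allocation overhead dominates.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct PiNet {
  int D;
  arma::uword h, h2, m, d;
  std::vector<arma::mat> A;
  std::vector<arma::rowvec> a;
  arma::mat M, W;
  arma::rowvec mb;

  PiNet(const arma::vec& theta, int D_, arma::uword h_, arma::uword h2_,
        arma::uword m_, arma::uword d_)
      : D(D_), h(h_), h2(h2_), m(m_), d(d_), A(D_), a(D_) {
    arma::uword pos = 0;
    for (int k = 0; k < D; ++k) {
      A[k] = arma::reshape(theta.subvec(pos, pos + h * d - 1), h, d);
      pos += h * d;
      a[k] = theta.subvec(pos, pos + h - 1).t();
      pos += h;
    }
    M = arma::reshape(theta.subvec(pos, pos + h2 * h - 1), h2, h);
    pos += h2 * h;
    mb = theta.subvec(pos, pos + h2 - 1).t();
    pos += h2;
    W = arma::reshape(theta.subvec(pos, pos + m * h2 - 1), m, h2);
  }

  arma::uword n_params() const {
    return D * (d + 1) * h + h2 * (h + 1) + m * h2;
  }

  // forward pass over rows of X, keeping intermediates for the reverse pass
  arma::mat forward(const arma::mat& X, std::vector<arma::mat>& U,
                    std::vector<arma::mat>& Z, arma::mat& Zm) const {
    U.resize(D); Z.resize(D);
    for (int k = 0; k < D; ++k) {
      U[k] = X * A[k].t();
      U[k].each_row() += a[k];
      Z[k] = (k == 0) ? U[0] : U[k] % Z[k - 1] + Z[k - 1];
    }
    Zm = Z[D - 1] * M.t();
    Zm.each_row() += mb;
    return Zm * W.t();
  }

  // reverse pass: gradient of sum_ij w(i,j) * y_j(x_i) w.r.t. theta
  arma::vec vjp(const arma::mat& X, const arma::mat& w,
                const std::vector<arma::mat>& U,
                const std::vector<arma::mat>& Z,
                const arma::mat& Zm) const {
    arma::mat gW = w.t() * Zm;
    arma::mat G = w * W;
    arma::mat gM = G.t() * Z[D - 1];
    arma::rowvec gmb = arma::sum(G, 0);
    G = G * M;
    arma::vec grad(n_params());
    std::vector<arma::mat> gA(D);
    std::vector<arma::rowvec> ga(D);
    for (int k = D - 1; k >= 0; --k) {
      arma::mat gradU = (k == 0) ? G : G % Z[k - 1];
      gA[k] = gradU.t() * X;
      ga[k] = arma::sum(gradU, 0);
      if (k > 0) G = G % (U[k] + 1.0);
    }
    arma::uword pos = 0;
    for (int k = 0; k < D; ++k) {
      grad.subvec(pos, pos + h * d - 1) = arma::vectorise(gA[k]);
      pos += h * d;
      grad.subvec(pos, pos + h - 1) = ga[k].t();
      pos += h;
    }
    grad.subvec(pos, pos + h2 * h - 1) = arma::vectorise(gM);
    pos += h2 * h;
    grad.subvec(pos, pos + h2 - 1) = gmb.t();
    pos += h2;
    grad.subvec(pos, pos + m * h2 - 1) = arma::vectorise(gW);
    return grad;
  }
};

}  // namespace

// SSE and its gradient (in the flat pinet_pack layout) for
// y = pinet(X) against targets Y.
// [[Rcpp::export]]
List pinet_sse_grad_cpp(const arma::vec& theta, const int D,
                        const arma::uword h, const arma::uword h2,
                        const arma::uword m, const arma::mat& X,
                        const arma::mat& Y) {
  PiNet net(theta, D, h, h2, m, X.n_cols);
  std::vector<arma::mat> U, Z;
  arma::mat Zm;
  arma::mat r = net.forward(X, U, Z, Zm) - Y;
  const double sse = arma::accu(r % r);
  arma::vec grad = net.vjp(X, 2.0 * r, U, Z, Zm);
  return List::create(Named("sse") = sse, Named("grad") = grad);
}

// Same objective through monomial sufficient statistics: the network
// output is an exact polynomial of degree <= the basis, so the SSE over n
// data points equals a quadratic form in the M expanded coefficients
// c_j = Vinv * y(Xc)_j, where Xc holds M collocation points and
// V = design(Xc).  G2 = B'B, By = B'Y, yss = sum(Y^2) for the full design
// matrix B.  The network is only ever evaluated at the M collocation
// points, independent of n.
// [[Rcpp::export]]
List pinet_proj_sse_grad_cpp(const arma::vec& theta, const int D,
                             const arma::uword h, const arma::uword h2,
                             const arma::uword m, const arma::mat& Xc,
                             const arma::mat& Vinv, const arma::mat& G2,
                             const arma::mat& By, const double yss) {
  PiNet net(theta, D, h, h2, m, Xc.n_cols);
  std::vector<arma::mat> U, Z;
  arma::mat Zm;
  arma::mat E = net.forward(Xc, U, Z, Zm);   // M x m, outputs at Xc
  arma::mat C = Vinv * E;                    // M x m expanded coefficients
  arma::mat G2C = G2 * C;
  const double sse =
      arma::accu(C % G2C) - 2.0 * arma::accu(C % By) + yss;
  arma::mat w = Vinv.t() * (2.0 * (G2C - By));  // d SSE / d E
  arma::vec grad = net.vjp(Xc, w, U, Z, Zm);
  return List::create(Named("sse") = sse, Named("grad") = grad);
}
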