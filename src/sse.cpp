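// State-dependent speciation/extinction (BiSSE/MuSSE) likelihood.
// Backward integration of the coupled extinction (E) and data (D) ODEs
// along each branch with an adaptive Cash-Karp 4(5) stepper, node
// combination D = lambda * D_left * D_right, per-node log rescaling,
// and state-weighted root treatment with optional conditioning on
// survival of the two root lineages.
#include "viviphy.h"
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct SseSystem {
  int k;
  arma::vec lambda, mu, qrow;  // qrow = total outflow of transitions
  arma::mat Q;                 // off-diagonal transition rates
  void deriv(const arma::vec& y, arma::vec& dy) const {
    // y = (E_1..E_k, D_1..D_k)
    for (int i = 0; i < k; ++i) {
      double qe = 0.0, qd = 0.0;
      for (int j = 0; j < k; ++j) {
        if (j == i) continue;
        qe += Q(i, j) * y(j);
        qd += Q(i, j) * y(k + j);
      }
      const double tot = lambda(i) + mu(i) + qrow(i);
      dy(i) = mu(i) - tot * y(i) + lambda(i) * y(i) * y(i) + qe;
      dy(k + i) = -tot * y(k + i) + 2.0 * lambda(i) * y(i) * y(k + i) + qd;
    }
  }
};

// Cash-Karp tableau
const double b2[] = {0.2};
const double b3[] = {3.0 / 40, 9.0 / 40};
const double b4[] = {0.3, -0.9, 1.2};
const double b5[] = {-11.0 / 54, 2.5, -70.0 / 27, 35.0 / 27};
const double b6[] = {1631.0 / 55296, 175.0 / 512, 575.0 / 13824,
                     44275.0 / 110592, 253.0 / 4096};
const double c5[] = {37.0 / 378, 0, 250.0 / 621, 125.0 / 594, 0, 512.0 / 1771};
const double c4[] = {2825.0 / 27648, 0, 18575.0 / 48384, 13525.0 / 55296,
                     277.0 / 14336, 0.25};

// integrate y over [0, len]; returns false on breakdown
bool integrate(const SseSystem& sys, arma::vec& y, double len,
               double rtol, double atol) {
  if (len <= 0.0) return true;
  const int n = y.n_elem, k = sys.k;
  arma::vec k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), yt(n), y5(n), y4(n);
  double t = 0.0, h = len;  // error control shrinks the step as needed
  int steps = 0;
  while (t < len) {
    if (++steps > 20000) return false;  // pathological stiffness
    if (t + h > len) h = len - t;
    sys.deriv(y, k1);
    yt = y + h * b2[0] * k1;
    sys.deriv(yt, k2);
    yt = y + h * (b3[0] * k1 + b3[1] * k2);
    sys.deriv(yt, k3);
    yt = y + h * (b4[0] * k1 + b4[1] * k2 + b4[2] * k3);
    sys.deriv(yt, k4);
    yt = y + h * (b5[0] * k1 + b5[1] * k2 + b5[2] * k3 + b5[3] * k4);
    sys.deriv(yt, k5);
    yt = y + h * (b6[0] * k1 + b6[1] * k2 + b6[2] * k3 + b6[3] * k4 + b6[4] * k5);
    sys.deriv(yt, k6);
    y5 = y + h * (c5[0] * k1 + c5[2] * k3 + c5[3] * k4 + c5[5] * k6);
    y4 = y + h * (c4[0] * k1 + c4[2] * k3 + c4[3] * k4 + c4[4] * k5 + c4[5] * k6);
    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      const double sc = atol + rtol * std::max(std::abs(y(i)), std::abs(y5(i)));
      err = std::max(err, std::abs(y5(i) - y4(i)) / sc);
    }
    if (!std::isfinite(err)) return false;
    if (err <= 1.0) {
      t += h;
      y = y5;
      for (int i = 0; i < k; ++i)        // extinction probs stay in [0,1]
        y(i) = std::min(1.0, std::max(0.0, y(i)));
      for (int i = k; i < n; ++i)
        if (y(i) < 0.0) y(i) = 0.0;
    }
    const double fac = err > 0.0
      ? 0.9 * std::pow(err, -0.2) : 5.0;
    h *= std::min(5.0, std::max(0.2, fac));
    if (h < 1e-14 * len) return false;
  }
  return true;
}

}  // namespace

// tipD: nTip x k initial D values (sampling fraction already applied);
// e0: length-k initial extinction values (1 - f).
// root_mode: 0 equal weights, 1 FitzJohn, 2 supplied root_prior.
// [[Rcpp::export]]
List sse_loglik_cpp(const arma::imat& edge, const arma::vec& el,
                    const arma::mat& tipD, const arma::vec& e0,
                    const arma::vec& lambda, const arma::vec& mu,
                    const arma::mat& Q, int root_mode,
                    const arma::vec& root_prior, bool cond_surv,
                    double rtol = 1e-8, double atol = 1e-8) {
  const int k = lambda.n_elem, nTip = tipD.n_rows, nEdge = edge.n_rows;
  const int nNode = edge.max();
  SseSystem sys{k, lambda, mu, arma::vec(k), Q};
  for (int i = 0; i < k; ++i) {
    double s = 0.0;
    for (int j = 0; j < k; ++j) if (j != i) s += Q(i, j);
    sys.qrow(i) = s;
  }
  arma::mat D(nNode, k, arma::fill::ones), E(nNode, k, arma::fill::zeros);
  arma::ivec nchild(nNode, arma::fill::zeros);
  D.rows(0, nTip - 1) = tipD;
  for (int i = 0; i < nTip; ++i) E.row(i) = e0.t();
  double logscale = 0.0;

  for (int e = 0; e < nEdge; ++e) {
    const int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    arma::vec y(2 * k);
    y.subvec(0, k - 1) = E.row(ch).t();
    y.subvec(k, 2 * k - 1) = D.row(ch).t();
    if (!integrate(sys, y, el(e), rtol, atol))
      return List::create(_["loglik"] = R_NegInf);
    const double mx = y.subvec(k, 2 * k - 1).max();
    if (mx <= 0.0 || !std::isfinite(mx))
      return List::create(_["loglik"] = R_NegInf);
    logscale += std::log(mx);
    if (nchild(par) == 0) {
      D.row(par) = y.subvec(k, 2 * k - 1).t() / mx;
      E.row(par) = y.subvec(0, k - 1).t();
    } else {
      D.row(par) %= y.subvec(k, 2 * k - 1).t() / mx;
      D.row(par) %= lambda.t();  // speciation at the combining node
    }
    ++nchild(par);
  }

  const int root = edge(nEdge - 1, 0) - 1;
  arma::vec Dr = D.row(root).t(), Er = E.row(root).t();
  arma::vec w(k);
  if (root_mode == 1) {
    const double s = arma::accu(Dr);
    if (s <= 0.0) return List::create(_["loglik"] = R_NegInf);
    w = Dr / s;
  } else if (root_mode == 2) {
    w = root_prior;
  } else {
    w.fill(1.0 / k);
  }
  double lik = 0.0;
  for (int i = 0; i < k; ++i) {
    double term = w(i) * Dr(i);
    if (cond_surv) {
      const double denom = lambda(i) * (1.0 - Er(i)) * (1.0 - Er(i));
      term = denom > 0.0 ? term / denom : 0.0;
    }
    lik += term;
  }
  if (lik <= 0.0) return List::create(_["loglik"] = R_NegInf);
  return List::create(_["loglik"] = std::log(lik) + logscale,
                      _["root_D"] = Dr, _["root_E"] = Er);
}
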