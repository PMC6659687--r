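// Felsenstein pruning for k-state continuous-time Markov (Mk) characters.
// Trees arrive as ape-style postorder edge matrices (1-based indices,
// tips 1..nTip, root nTip+1).  Per-node rescaling keeps likelihoods finite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// P(t) = exp(Q t); 2-state case closed form, otherwise scaling-and-squaring.
arma::mat mk_pmat(const arma::mat& Q, double t) {
  const int k = Q.n_rows;
  if (t <= 0.0) return arma::eye(k, k);
  if (k == 2) {
    const double a = Q(0, 1), b = Q(1, 0), s = a + b;
    arma::mat P(2, 2);
    if (s <= 0.0) { P.eye(); return P; }
    const double e = std::exp(-s * t);
    P(0, 0) = (b + a * e) / s;  P(0, 1) = (a - a * e) / s;
    P(1, 0) = (b - b * e) / s;  P(1, 1) = (a + b * e) / s;
    return P;
  }
  arma::mat P = arma::expmat(Q * t);
  P.elem(arma::find(P < 0)).zeros();
  return P;
}

// [[Rcpp::export]]
arma::mat mk_pmat_cpp(const arma::mat& Q, double t) { return mk_pmat(Q, t); }

// Down-pass partial likelihoods.  tipL: nTip x k partial likelihoods at the
// tips (indicator rows, or all-ones for ambiguous/missing tips).
// root_mode: 0 = uniform, 1 = FitzJohn, 2 = supplied root_prior.
// Returns log-likelihood, and optionally the (rescaled) partials.
// [[Rcpp::export]]
List mk_pruning_cpp(const arma::imat& edge, const arma::vec& el,
                    const arma::mat& tipL, const arma::mat& Q,
                    int root_mode, const arma::vec& root_prior,
                    bool return_partials = false) {
  const int k = Q.n_rows;
  const int nTip = tipL.n_rows;
  const int nEdge = edge.n_rows;
  const int nNode = edge.max();  // total node count (tips + internals)
  arma::mat part(nNode, k, arma::fill::ones);
  part.rows(0, nTip - 1) = tipL;
  double logscale = 0.0;

  for (int e = 0; e < nEdge; ++e) {
    const int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    arma::mat P = mk_pmat(Q, el(e));
    arma::vec v = P * part.row(ch).t();
    const double m = v.max();
    if (m <= 0.0) {
      // data impossible under this model (e.g. zero-length conflict)
      return List::create(_["loglik"] = R_NegInf);
    }
    v /= m;
    logscale += std::log(m);
    part.row(par) %= v.t();
  }

  const int root = edge(nEdge - 1, 0) - 1;
  arma::vec Lr = part.row(root).t();
  double lik;
  if (root_mode == 1) {
    const double s = arma::accu(Lr);
    lik = s > 0 ? arma::dot(Lr / s, Lr) : 0.0;
  } else if (root_mode == 2) {
    lik = arma::dot(root_prior, Lr);
  } else {
    lik = arma::accu(Lr) / k;
  }
  double ll = lik > 0 ? std::log(lik) + logscale : R_NegInf;
  if (!return_partials) return List::create(_["loglik"] = ll);
  return List::create(_["loglik"] = ll, _["partials"] = part);
}
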