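// Reversible-jump MCMC for Pagel-type correlated evolution of two binary
// traits on a 4-state joint chain (states (0,0),(0,1),(1,0),(1,1)).
// Dual transitions (both traits changing at once) carry rate zero.
// Each transition rate is either in the zero bin or free, with an
// exponential prior whose mean is itself sampled from U(0, 20)
// (hierarchical hyperprior); birth proposals draw from the prior so the
// prior density cancels in the acceptance ratio.  A power-posterior
// exponent on the likelihood makes the same kernel serve the
// stepping-stone sampler.
#include "viviphy.h"
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill the 4x4 generator from the parameter vector.
// family 0: independent, params (a1, b1, a2, b2) = gain/loss of trait 1/2.
// family 1: dependent, params (q12,q13,q21,q24,q31,q34,q42,q43).
static void build_Q(const arma::vec& v, int family, arma::mat& Q) {
  Q.zeros(4, 4);
  if (family == 0) {
    Q(0, 2) = Q(1, 3) = v(0);  // trait 1 gain
    Q(2, 0) = Q(3, 1) = v(1);  // trait 1 loss
    Q(0, 1) = Q(2, 3) = v(2);  // trait 2 gain
    Q(1, 0) = Q(3, 2) = v(3);  // trait 2 loss
  } else {
    Q(0, 1) = v(0); Q(0, 2) = v(1);
    Q(1, 0) = v(2); Q(1, 3) = v(3);
    Q(2, 0) = v(4); Q(2, 3) = v(5);
    Q(3, 1) = v(6); Q(3, 2) = v(7);
  }
  Q.diag() = -arma::sum(Q, 1);
}

// Pruning log-likelihood with a per-generator eigendecomposition; falls
// back to scaling-and-squaring when Q is (near-)defective.
static double q_loglik(const arma::imat& edge, const arma::vec& el,
                       const arma::mat& tipL, const arma::mat& Q,
                       int root_mode, const arma::vec& root_prior) {
  const int k = 4, nTip = tipL.n_rows, nEdge = edge.n_rows;
  arma::cx_vec d;
  arma::cx_mat V, Vinv;
  bool eig_ok = arma::eig_gen(d, V, Q);
  if (eig_ok) eig_ok = arma::inv(Vinv, V);
  if (eig_ok) {
    arma::mat recon = arma::real(V * arma::diagmat(d) * Vinv);
    if (arma::norm(recon - Q, "fro") > 1e-8 * (1.0 + arma::norm(Q, "fro")))
      eig_ok = false;
  }
  const int nNode = edge.max();
  arma::mat part(nNode, k, arma::fill::ones);
  part.rows(0, nTip - 1) = tipL;
  double logscale = 0.0;
  arma::mat P(k, k);
  for (int e = 0; e < nEdge; ++e) {
    const int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    if (eig_ok) {
      P = arma::real(V * arma::diagmat(arma::exp(d * el(e))) * Vinv);
      P.elem(arma::find(P < 0)).zeros();
    } else {
      P = mk_pmat(Q, el(e));
    }
    arma::vec u = P * part.row(ch).t();
    const double m = u.max();
    if (m <= 0.0 || !std::isfinite(m)) return R_NegInf;
    u /= m;
    logscale += std::log(m);
    part.row(par) %= u.t();
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
  return lik > 0 ? std::log(lik) + logscale : R_NegInf;
}

// [[Rcpp::export]]
double pagel_loglik_cpp(const arma::imat& edge, const arma::vec& el,
                        const arma::mat& tipL, const arma::vec& params,
                        int family, int root_mode, const arma::vec& root_prior) {
  arma::mat Q;
  build_Q(params, family, Q);
  return q_loglik(edge, el, tipL, Q, root_mode, root_prior);
}

static inline double dexp_mean(double x, double m) {
  return -std::log(m) - x / m;
}

// [[Rcpp::export]]
List discrete_mcmc_cpp(const arma::imat& edge, const arma::vec& el,
                       const arma::mat& tipL, int family,
                       int n_iter, int burnin, int thin,
                       bool rj, bool hyper, double prior_mean,
                       double beta_power, bool use_lik,
                       arma::vec init_vals, arma::ivec init_z,
                       double init_m, int root_mode, arma::vec root_prior) {
  RNGScope scope;
  const int np = family == 0 ? 4 : 8;
  const double hyper_max = 20.0, p_zero = 0.5, step_sd = 0.6;
  arma::vec v = init_vals;          // rate values (used only where z = 1)
  arma::ivec z = init_z;            // 1 = free, 0 = zero bin
  double m = hyper ? init_m : prior_mean;
  const bool lik_on = use_lik && beta_power > 0.0;

  arma::mat Q;
  arma::vec cur = v % arma::conv_to<arma::vec>::from(z);
  double ll = 0.0;
  if (lik_on) {
    build_Q(cur, family, Q);
    ll = q_loglik(edge, el, tipL, Q, root_mode, root_prior);
  }

  const int n_keep = (n_iter - burnin) / thin;
  arma::mat out(n_keep, np + 2);    // m, rates, loglik
  int kept = 0;
  long acc_val = 0, try_val = 0, acc_rj = 0, try_rj = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // rate-value updates (multiplicative random walk on free rates)
    for (int i = 0; i < np; ++i) {
      if (!z(i)) continue;
      ++try_val;
      const double vi = v(i);
      const double vp = vi * std::exp(R::rnorm(0.0, step_sd));
      double lr = dexp_mean(vp, m) - dexp_mean(vi, m) + std::log(vp / vi);
      double llp = ll;
      if (lik_on) {
        arma::vec cand = cur; cand(i) = vp;
        build_Q(cand, family, Q);
        llp = q_loglik(edge, el, tipL, Q, root_mode, root_prior);
        lr += beta_power * (llp - ll);
      }
      if (std::isfinite(lr) && std::log(R::runif(0.0, 1.0)) < lr) {
        v(i) = vp; cur(i) = vp; ll = llp; ++acc_val;
      }
    }
    // reversible-jump toggle of one rate between the zero bin and free
    if (rj) {
      ++try_rj;
      const int i = static_cast<int>(R::runif(0.0, 1.0) * np) % np;
      if (z(i)) {  // death: prior density cancels the reverse birth proposal
        double lr = std::log(p_zero / (1.0 - p_zero));
        double llp = ll;
        if (lik_on) {
          arma::vec cand = cur; cand(i) = 0.0;
          build_Q(cand, family, Q);
          llp = q_loglik(edge, el, tipL, Q, root_mode, root_prior);
          lr += beta_power * (llp - ll);
        }
        if (std::isfinite(lr) && std::log(R::runif(0.0, 1.0)) < lr) {
          z(i) = 0; cur(i) = 0.0; ll = llp; ++acc_rj;
        }
      } else {     // birth: draw the new rate from its prior
        const double vp = R::rexp(m);
        double lr = std::log((1.0 - p_zero) / p_zero);
        double llp = ll;
        if (lik_on) {
          arma::vec cand = cur; cand(i) = vp;
          build_Q(cand, family, Q);
          llp = q_loglik(edge, el, tipL, Q, root_mode, root_prior);
          lr += beta_power * (llp - ll);
        }
        if (std::isfinite(lr) && std::log(R::runif(0.0, 1.0)) < lr) {
          z(i) = 1; v(i) = vp; cur(i) = vp; ll = llp; ++acc_rj;
        }
      }
    }
    // hyperprior mean: independence proposal from U(0, hyper_max)
    if (hyper) {
      const double mp = R::runif(0.0, hyper_max);
      double lr = 0.0;
      for (int i = 0; i < np; ++i)
        if (z(i)) lr += dexp_mean(v(i), mp) - dexp_mean(v(i), m);
      if (std::log(R::runif(0.0, 1.0)) < lr) m = mp;
    }

    if (it > burnin && (it - burnin) % thin == 0 && kept < n_keep) {
      out(kept, 0) = m;
      for (int i = 0; i < np; ++i) out(kept, 1 + i) = cur(i);
      double ll_rec = ll;
      if (use_lik && !lik_on) {  // prior stone still records the likelihood
        build_Q(cur, family, Q);
        ll_rec = q_loglik(edge, el, tipL, Q, root_mode, root_prior);
      }
      out(kept, np + 1) = use_lik ? ll_rec : NA_REAL;
      ++kept;
    }
  }
  if (kept < n_keep) out = out.rows(0, std::max(kept - 1, 0));
  return List::create(
    _["samples"] = out,
    _["final_vals"] = v, _["final_z"] = z, _["final_m"] = m,
    _["accept_value"] = try_val ? double(acc_val) / try_val : NA_REAL,
    _["accept_jump"] = try_rj ? double(acc_rj) / try_rj : NA_REAL);
}
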