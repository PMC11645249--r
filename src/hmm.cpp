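#include <RcppArmadillo.h>
#include "states.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace exonstate;

// Scaled forward-backward over the 23-edge transition graph.
//
// lik: T x 15 (already masked + smoothed emission likelihoods), A: 15 x 15
// row-stochastic with support on the edge set, init/fin: length-15
// non-negative boundary weight vectors. Returns posteriors gamma (rows sum to
// 1), the data log-likelihood, and the scaled intermediates needed by the VJP.
// [[Rcpp::export]]
List cpp_forward_backward(const arma::mat& lik, const arma::mat& A,
                          const arma::vec& init, const arma::vec& fin) {
  const int T = lik.n_rows;
  const int S = N_STATES;
  if ((int)lik.n_cols != S) stop("likelihood matrix must have 15 columns");

  arma::mat u(T, S), alpha(T, S), beta(T, S), gamma(T, S);
  arma::vec c(T), d(T), sg(T);

  // forward
  for (int t = 0; t < T; ++t) {
    arma::rowvec ut(S, arma::fill::zeros);
    if (t == 0) {
      ut = init.t();
    } else {
      for (int e = 0; e < N_EDGES; ++e)
        ut(EDGE_TO[e]) += A(EDGE_FROM[e], EDGE_TO[e]) * alpha(t - 1, EDGE_FROM[e]);
    }
    u.row(t) = ut;
    arma::rowvec v = ut % lik.row(t);
    double ct = arma::accu(v);
    if (!(ct > 0.0))
      stop("no positive-probability path at position %d (all states masked or unreachable)", t + 1);
    c(t) = ct;
    alpha.row(t) = v / ct;
  }

  // backward (final weights folded into beta at T-1)
  {
    double dT = arma::accu(fin);
    if (!(dT > 0.0)) stop("final state distribution has no mass");
    d(T - 1) = dT;
    beta.row(T - 1) = fin.t() / dT;
  }
  for (int t = T - 2; t >= 0; --t) {
    arma::rowvec w(S, arma::fill::zeros);
    arma::rowvec bb = beta.row(t + 1) % lik.row(t + 1);
    for (int e = 0; e < N_EDGES; ++e)
      w(EDGE_FROM[e]) += A(EDGE_FROM[e], EDGE_TO[e]) * bb(EDGE_TO[e]);
    double dt = arma::accu(w);
    if (!(dt > 0.0))
      stop("no positive-probability path through position %d", t + 1);
    d(t) = dt;
    beta.row(t) = w / dt;
  }

  double tail = arma::accu(alpha.row(T - 1) % fin.t());
  if (!(tail > 0.0)) stop("no path reaches an allowed final state");
  double loglik = arma::accu(arma::log(c)) + std::log(tail);

  for (int t = 0; t < T; ++t) {
    arma::rowvec p = alpha.row(t) % beta.row(t);
    double st = arma::accu(p);
    if (!(st > 0.0)) stop("posterior mass vanished at position %d", t + 1);
    sg(t) = st;
    gamma.row(t) = p / st;
  }

  return List::create(
    _["gamma"] = gamma, _["loglik"] = loglik,
    _["u"] = u, _["alpha"] = alpha, _["beta"] = beta,
    _["c"] = c, _["d"] = d, _["s"] = sg);
}

// Vector-Jacobian product of the posteriors with respect to the emission
// likelihoods: given dL/dgamma, return dL/dlik. The per-step scaling constants
// are treated as constants, which is exact because the posteriors are
// invariant to any positive rescaling of the forward/backward variables.
// [[Rcpp::export]]
arma::mat cpp_forward_backward_vjp(const arma::mat& lik, const arma::mat& A,
                                   const arma::vec& init, const arma::vec& fin,
                                   const List& cache, const arma::mat& dgamma) {
  const int T = lik.n_rows;
  const int S = N_STATES;
  arma::mat u = cache["u"], alpha = cache["alpha"], beta = cache["beta"],
            gamma = cache["gamma"];
  arma::vec c = cache["c"], d = cache["d"], sg = cache["s"];

  arma::mat galpha(T, S, arma::fill::zeros), gbeta(T, S, arma::fill::zeros),
            dlik(T, S, arma::fill::zeros);

  // gamma_t = p_t / s_t with p_t = alpha_t % beta_t
  for (int t = 0; t < T; ++t) {
    double dot = arma::accu(dgamma.row(t) % gamma.row(t));
    arma::rowvec dp = (dgamma.row(t) - dot) / sg(t);
    galpha.row(t) += dp % beta.row(t);
    gbeta.row(t) += dp % alpha.row(t);
  }

  // adjoint of the backward recursion, traversed in increasing t
  // beta_t = (A (lik_{t+1} % beta_{t+1})) / d_t
  for (int t = 0; t < T - 1; ++t) {
    arma::rowvec gb = gbeta.row(t) / d(t);
    for (int e = 0; e < N_EDGES; ++e) {
      int p = EDGE_FROM[e], q = EDGE_TO[e];
      double apq = A(p, q);
      dlik(t + 1, q) += gb(p) * apq * beta(t + 1, q);
      gbeta(t + 1, q) += gb(p) * apq * lik(t + 1, q);
    }
  }

  // adjoint of the forward recursion, traversed in decreasing t
  // alpha_t = (u_t % lik_t) / c_t,  u_t = A' alpha_{t-1} (u_0 = init)
  for (int t = T - 1; t >= 0; --t) {
    arma::rowvec ga = galpha.row(t) / c(t);
    dlik.row(t) += ga % u.row(t);
    arma::rowvec gu = ga % lik.row(t);
    if (t > 0) {
      for (int e = 0; e < N_EDGES; ++e) {
        int p = EDGE_FROM[e], q = EDGE_TO[e];
        galpha(t - 1, p) += A(p, q) * gu(q);
      }
    }
  }

  return dlik;
}
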