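#include <RcppArmadillo.h>
#include "states.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace exonstate;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// One sequential Viterbi sweep over rows [a, b) of loglik. delta0 seeds the
// DP at row a: if prev_seed is true, delta0 holds scores of states at row
// a - 1 and a transition is applied; otherwise delta0 is added directly to the
// emissions of row a (initial-distribution seeding). psi stores, per row, the
// argmax predecessor with the shared tie-break: predecessors are scanned in
// increasing state index and replaced only on strictly greater score, so the
// lowest state index wins ties everywhere.
static void local_sweep(const arma::mat& loglik, const arma::mat& logA,
                        const arma::rowvec& delta0, bool prev_seed,
                        int a, int b, arma::rowvec& delta, arma::imat& psi) {
  const int S = N_STATES;
  arma::rowvec cur(S);
  if (prev_seed) {
    cur.fill(NEG_INF);
    arma::irowvec arg(S);
    arg.fill(-1);
    for (int e = 0; e < N_EDGES; ++e) {
      int p = EDGE_FROM[e], q = EDGE_TO[e];
      double s = delta0(p) + logA(p, q);
      if (s > cur(q)) { cur(q) = s; arg(q) = p; }
    }
    for (int q = 0; q < S; ++q) {
      cur(q) = (cur(q) == NEG_INF) ? NEG_INF : cur(q) + loglik(a, q);
      psi(0, q) = arg(q);
    }
  } else {
    for (int q = 0; q < S; ++q) {
      cur(q) = delta0(q) + loglik(a, q);
      psi(0, q) = -1;
    }
  }
  arma::rowvec nxt(S);
  for (int t = a + 1; t < b; ++t) {
    nxt.fill(NEG_INF);
    arma::irowvec arg(S);
    arg.fill(-1);
    for (int e = 0; e < N_EDGES; ++e) {
      int p = EDGE_FROM[e], q = EDGE_TO[e];
      if (cur(p) == NEG_INF) continue;
      double s = cur(p) + logA(p, q);
      if (s > nxt(q)) { nxt(q) = s; arg(q) = p; }
    }
    for (int q = 0; q < S; ++q) {
      nxt(q) = (nxt(q) == NEG_INF) ? NEG_INF : nxt(q) + loglik(t, q);
      psi(t - a, q) = arg(q);
    }
    cur = nxt;
  }
  delta = cur;
}

static int argmax_lowest(const arma::rowvec& v) {
  int best = -1;
  double bs = NEG_INF;
  for (int q = 0; q < (int)v.n_elem; ++q)
    if (v(q) > bs) { bs = v(q); best = q; }
  return best;
}

// [[Rcpp::export]]
List cpp_viterbi(const arma::mat& loglik, const arma::mat& logA,
                 const arma::vec& loginit, const arma::vec& logfinal) {
  const int T = loglik.n_rows;
  const int S = N_STATES;
  arma::rowvec delta(S);
  arma::imat psi(T, S);
  local_sweep(loglik, logA, loginit.t(), false, 0, T, delta, psi);
  arma::rowvec fin = delta + logfinal.t();
  int q = argmax_lowest(fin);
  if (q < 0 || fin(q) == NEG_INF)
    stop("no positive-probability path (all states masked or unreachable)");
  double score = fin(q);
  IntegerVector path(T);
  for (int t = T - 1; t >= 0; --t) {
    path[t] = q + 1;
    if (t > 0) q = psi(t, q);
  }
  return List::create(_["path"] = path, _["score"] = score);
}

// Segment-parallel Viterbi. Each segment k >= 1 is summarised independently by
// a 15 x 15 max-plus matrix M_k[p, q] = best score of any in-segment path that
// enters from state p at the last position of segment k - 1 and ends in state
// q, including the crossing transition and all in-segment emissions and
// transitions. The global pass folds the summaries left to right with max-plus
// products, one step per segment, recovering the exact sequential Viterbi
// scores at every segment border. The path is reconstructed by re-running the
// chosen segments seeded with the border score vectors, so backtracking makes
// the same tie-break choices as the sequential decoder.
// [[Rcpp::export]]
List cpp_viterbi_parallel(const arma::mat& loglik, const arma::mat& logA,
                          const arma::vec& loginit, const arma::vec& logfinal,
                          int segment_length) {
  const int T = loglik.n_rows;
  const int S = N_STATES;
  if (segment_length < 2) stop("segment_length must be >= 2");
  const int K = (T + segment_length - 1) / segment_length;

  // per-segment summaries (independent per segment; parallelizable contract)
  arma::mat G(K, S);
  {
    arma::rowvec delta(S);
    arma::imat psi(segment_length, S);
    local_sweep(loglik, logA, loginit.t(), false, 0,
                std::min(segment_length, T), delta, psi);
    G.row(0) = delta;
  }
  for (int k = 1; k < K; ++k) {
    int a = k * segment_length, b = std::min(a + segment_length, T);
    arma::mat M(S, S);
    arma::imat psi(b - a, S);
    for (int p = 0; p < S; ++p) {
      arma::rowvec seed(S);
      seed.fill(NEG_INF);
      seed(p) = 0.0;
      arma::rowvec delta(S);
      local_sweep(loglik, logA, seed, true, a, b, delta, psi);
      M.row(p) = delta;
    }
    // global step: max-plus product G_k = G_{k-1} (x) M_k
    arma::rowvec g(S);
    g.fill(NEG_INF);
    for (int q = 0; q < S; ++q)
      for (int p = 0; p < S; ++p) {
        if (G(k - 1, p) == NEG_INF || M(p, q) == NEG_INF) continue;
        double s = G(k - 1, p) + M(p, q);
        if (s > g(q)) g(q) = s;
      }
    G.row(k) = g;
  }

  arma::rowvec fin = G.row(K - 1) + logfinal.t();
  int q = argmax_lowest(fin);
  if (q < 0 || fin(q) == NEG_INF)
    stop("no positive-probability path (all states masked or unreachable)");
  double score = fin(q);

  // reconstruction: re-run each chosen segment seeded with the exact border
  // score vector, then backtrack through its psi table
  IntegerVector path(T);
  for (int k = K - 1; k >= 0; --k) {
    int a = k * segment_length, b = std::min(a + segment_length, T);
    arma::rowvec delta(S);
    arma::imat psi(b - a, S);
    if (k == 0) {
      local_sweep(loglik, logA, loginit.t(), false, a, b, delta, psi);
    } else {
      local_sweep(loglik, logA, G.row(k - 1), true, a, b, delta, psi);
    }
    int qq = q;
    for (int t = b - 1; t >= a; --t) {
      path[t] = qq + 1;
      qq = psi(t - a, qq);
    }
    q = qq;  // state at the previous segment's last position
  }
  return List::create(_["path"] = path, _["score"] = score);
}

// Score a given path under the model: emissions plus transitions plus boundary
// weights (self-consistency checks).
// [[Rcpp::export]]
double cpp_path_score(const arma::mat& loglik, const arma::mat& logA,
                      const arma::vec& loginit, const arma::vec& logfinal,
                      IntegerVector path) {
  const int T = loglik.n_rows;
  double s = loginit(path[0] - 1) + loglik(0, path[0] - 1);
  for (int t = 1; t < T; ++t)
    s += logA(path[t - 1] - 1, path[t] - 1) + loglik(t, path[t] - 1);
  s += logfinal(path[T - 1] - 1);
  return s;
}
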