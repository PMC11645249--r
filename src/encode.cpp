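#include <Rcpp.h>
#include "states.h"

using namespace Rcpp;
using namespace exonstate;

// Column order of the one-hot nucleotide block: A, C, G, T, N.
static inline int base_index(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;  // N
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_encode_sequence(std::string seq, IntegerVector repeat_track) {
  int T = seq.size();
  if ((int)repeat_track.size() != T)
    stop("repeat track length does not match sequence length");
  NumericMatrix out(T, 6);
  for (int i = 0; i < T; ++i) {
    out(i, base_index(seq[i])) = 1.0;
    out(i, 5) = repeat_track[i] ? 1.0 : 0.0;
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_reverse_complement(std::string seq) {
  int T = seq.size();
  std::string out(T, 'N');
  for (int i = 0; i < T; ++i) {
    char c = seq[T - 1 - i];
    switch (c) {
      case 'A': out[i] = 'T'; break;
      case 'C': out[i] = 'G'; break;
      case 'G': out[i] = 'C'; break;
      case 'T': out[i] = 'A'; break;
      default:  out[i] = 'N'; break;
    }
  }
  return out;
}

static inline bool is_stop_triplet(const std::string& s, int i) {
  // triplet s[i..i+2]
  if (s[i] != 'T') return false;
  char b = s[i + 1], c = s[i + 2];
  return (b == 'A' && (c == 'A' || c == 'G')) || (b == 'G' && c == 'A');
}

// Per-position sequence constraint mask (T x 15, 1 = state allowed).
// START needs ATG at [i, i+2]; STOP a stop triplet ending at i; DSS_j a GT
// donor immediately downstream; ASS_j an AG acceptor immediately upstream.
// E2/DSS2 are forbidden where a stop triplet ends at i (codon position 2),
// which blocks in-frame stops inside an exon but not stops spliced across an
// intron. Non-coding states are never masked. Windows touching the sequence
// boundary or containing N do not license a signal state.
// [[Rcpp::export]]
IntegerMatrix cpp_constraint_mask(std::string seq) {
  int T = seq.size();
  IntegerMatrix mask(T, N_STATES);
  for (int i = 0; i < T; ++i) {
    mask(i, IR) = mask(i, I0) = mask(i, I1) = mask(i, I2) = 1;
    mask(i, E0) = mask(i, E1) = 1;

    bool stop_here = (i >= 2) && is_stop_triplet(seq, i - 2);
    mask(i, E2) = stop_here ? 0 : 1;

    if (i + 2 < T && seq[i] == 'A' && seq[i + 1] == 'T' && seq[i + 2] == 'G')
      mask(i, START) = 1;
    if (stop_here) mask(i, STOP) = 1;

    bool donor = (i + 2 < T) && seq[i + 1] == 'G' && seq[i + 2] == 'T';
    if (donor) {
      mask(i, DSS0) = 1;
      mask(i, DSS1) = 1;
      mask(i, DSS2) = stop_here ? 0 : 1;
    }
    bool acceptor = (i >= 2) && seq[i - 2] == 'A' && seq[i - 1] == 'G';
    if (acceptor) {
      mask(i, ASS0) = 1;
      mask(i, ASS1) = 1;
      mask(i, ASS2) = 1;
    }
  }
  return mask;
}

// [[Rcpp::export]]
List cpp_edge_list() {
  IntegerVector from(N_EDGES), to(N_EDGES);
  for (int e = 0; e < N_EDGES; ++e) {
    from[e] = EDGE_FROM[e] + 1;  // 1-based for R
    to[e] = EDGE_TO[e] + 1;
  }
  return List::create(_["from"] = from, _["to"] = to);
}

// Validate a label path against the 23-edge grammar. Returns 0 if valid,
// otherwise the 1-based position of the first offending label (a violation at
// position p means the pair (p-1, p) is not an edge; p = 1 flags an invalid
// start state and p = T + 1 an invalid end state).
// labels are 1-based state indices; check_boundaries toggles the requirement
// that the path starts and ends in IR.
// [[Rcpp::export]]
int cpp_grammar_violation(IntegerVector labels, bool check_boundaries) {
  int T = labels.size();
  if (T == 0) return 0;
  bool allowed[N_STATES][N_STATES] = {};
  for (int e = 0; e < N_EDGES; ++e) allowed[EDGE_FROM[e]][EDGE_TO[e]] = true;
  for (int i = 0; i < T; ++i)
    if (labels[i] < 1 || labels[i] > N_STATES) return i + 1;
  if (check_boundaries && labels[0] != IR + 1) return 1;
  for (int i = 1; i < T; ++i)
    if (!allowed[labels[i - 1] - 1][labels[i] - 1]) return i + 1;
  if (check_boundaries && labels[T - 1] != IR + 1) return T + 1;
  return 0;
}
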