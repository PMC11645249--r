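#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// CNN -> biLSTM -> dense sequence-to-sequence network with manual
// backpropagation. Input is a T x 6 encoding (5 one-hot nucleotide columns +
// repeat track); output is a T x 15 row-stochastic class-probability matrix.
// A reshape by factor R between the convolutional stack and the LSTM pools R
// consecutive bases into one LSTM step; the dense head emits 15 logits per
// base. With use_residual the reshaped convolutional features are concatenated
// to the biLSTM output before the dense head (skip connection preserving local
// signal detail around the recurrent bottleneck).

using namespace Rcpp;

struct NNConfig {
  std::vector<int> conv_filters;
  std::vector<int> conv_dilations;
  int conv_width, R, U, layers;
  bool residual;
  double dropout;
};

static NNConfig parse_cfg(const List& cfg) {
  NNConfig c;
  IntegerVector f = cfg["conv_filters"];
  c.conv_filters = std::vector<int>(f.begin(), f.end());
  if (cfg.containsElementNamed("conv_dilations") &&
      !Rf_isNull(cfg["conv_dilations"])) {
    IntegerVector d = cfg["conv_dilations"];
    c.conv_dilations = std::vector<int>(d.begin(), d.end());
  } else {
    c.conv_dilations = std::vector<int>(c.conv_filters.size(), 1);
  }
  if (c.conv_dilations.size() != c.conv_filters.size())
    stop("conv_dilations must match conv_filters in length");
  c.conv_width = as<int>(cfg["conv_width"]);
  c.R = as<int>(cfg["reshape_factor"]);
  c.U = as<int>(cfg["lstm_units"]);
  c.layers = as<int>(cfg["lstm_layers"]);
  c.residual = as<bool>(cfg["use_residual"]);
  c.dropout = as<double>(cfg["dropout"]);
  if (c.conv_width % 2 == 0) stop("conv_width must be odd");
  if (c.layers < 1 || c.layers > 2) stop("lstm_layers must be 1 or 2");
  return c;
}

struct Shape { std::string name; int rows, cols; };

static std::vector<Shape> param_shapes(const NNConfig& c) {
  std::vector<Shape> s;
  int in_ch = 6;
  for (size_t l = 0; l < c.conv_filters.size(); ++l) {
    int out_ch = c.conv_filters[l];
    s.push_back({"conv" + std::to_string(l + 1) + "_W", c.conv_width * in_ch, out_ch});
    s.push_back({"conv" + std::to_string(l + 1) + "_b", 1, out_ch});
    in_ch = out_ch;
  }
  int D0 = c.conv_filters.back() * c.R;
  int in_dim = D0;
  for (int l = 0; l < c.layers; ++l) {
    for (int dir = 0; dir < 2; ++dir) {
      std::string tag = "lstm" + std::to_string(l + 1) + (dir == 0 ? "_fwd" : "_bwd");
      s.push_back({tag + "_Wx", in_dim, 4 * c.U});
      s.push_back({tag + "_Wh", c.U, 4 * c.U});
      s.push_back({tag + "_b", 1, 4 * c.U});
    }
    in_dim = 2 * c.U;
  }
  int D = 2 * c.U + (c.residual ? D0 : 0);
  s.push_back({"dense_W", D, 15 * c.R});
  s.push_back({"dense_b", 1, 15 * c.R});
  return s;
}

// [[Rcpp::export]]
List cpp_nn_param_shapes(const List& cfg) {
  NNConfig c = parse_cfg(cfg);
  std::vector<Shape> s = param_shapes(c);
  CharacterVector names(s.size());
  IntegerVector rows(s.size()), cols(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    names[i] = s[i].name;
    rows[i] = s[i].rows;
    cols[i] = s[i].cols;
  }
  return List::create(_["name"] = names, _["rows"] = rows, _["cols"] = cols);
}

// non-owning views into the flat parameter vector, in shape order
static std::vector<arma::mat> param_views(double* p, const std::vector<Shape>& s) {
  std::vector<arma::mat> v;
  v.reserve(s.size());  // aux-memory views must never be copied by growth
  size_t off = 0;
  for (const Shape& sh : s) {
    v.emplace_back(p + off, sh.rows, sh.cols, false, true);
    off += (size_t)sh.rows * sh.cols;
  }
  return v;
}

static size_t total_params(const std::vector<Shape>& s) {
  size_t n = 0;
  for (const Shape& sh : s) n += (size_t)sh.rows * sh.cols;
  return n;
}

// same-padded (optionally dilated) 1D convolution via blocked im2col + gemm;
// tap w of a width-K kernel with dilation d reads offset (w - K/2) * d
static arma::mat conv1d_forward(const arma::mat& X, const arma::mat& W,
                                const arma::rowvec& b, int width, int dil) {
  const int T = X.n_rows, in_ch = X.n_cols, out_ch = W.n_cols;
  const int pad = width / 2, block = 8192;
  arma::mat out(T, out_ch);
  arma::mat col;
  for (int a = 0; a < T; a += block) {
    int bnd = std::min(a + block, T);
    col.zeros(bnd - a, width * in_ch);
    for (int w = 0; w < width; ++w) {
      int off = (w - pad) * dil;
      int lo = std::max(a + off, 0), hi = std::min(bnd + off, T);
      if (lo >= hi) continue;
      col.submat(lo - (a + off), w * in_ch, hi - 1 - (a + off),
                 (w + 1) * in_ch - 1) = X.rows(lo, hi - 1);
    }
    out.rows(a, bnd - 1) = col * W;
  }
  out.each_row() += b;
  return out;
}

static void conv1d_backward(const arma::mat& X, const arma::mat& W, int width,
                            int dil, const arma::mat& dOut, arma::mat& dX,
                            arma::mat& dW, arma::rowvec& db, bool need_dX) {
  const int T = X.n_rows, in_ch = X.n_cols;
  const int pad = width / 2, block = 8192;
  dW.zeros(W.n_rows, W.n_cols);
  db = arma::sum(dOut, 0);
  if (need_dX) dX.zeros(T, in_ch);
  arma::mat col, dcol;
  for (int a = 0; a < T; a += block) {
    int bnd = std::min(a + block, T);
    col.zeros(bnd - a, width * in_ch);
    for (int w = 0; w < width; ++w) {
      int off = (w - pad) * dil;
      int lo = std::max(a + off, 0), hi = std::min(bnd + off, T);
      if (lo >= hi) continue;
      col.submat(lo - (a + off), w * in_ch, hi - 1 - (a + off),
                 (w + 1) * in_ch - 1) = X.rows(lo, hi - 1);
    }
    const arma::mat dOb = dOut.rows(a, bnd - 1);
    dW += col.t() * dOb;
    if (need_dX) {
      dcol = dOb * W.t();
      for (int w = 0; w < width; ++w) {
        int off = (w - pad) * dil;
        int lo = std::max(a + off, 0), hi = std::min(bnd + off, T);
        if (lo >= hi) continue;
        dX.rows(lo, hi - 1) += dcol.submat(
            lo - (a + off), w * in_ch, hi - 1 - (a + off),
            (w + 1) * in_ch - 1);
      }
    }
  }
}

struct LSTMCache {
  arma::mat i, f, g, o, c, h;  // n x U each, in processing order
  bool reverse;
};

static arma::mat lstm_forward(const arma::mat& Xin, const arma::mat& Wx,
                              const arma::mat& Wh, const arma::rowvec& b,
                              bool reverse, LSTMCache& cache) {
  const int n = Xin.n_rows, U = Wh.n_rows;
  arma::mat X = reverse ? arma::flipud(Xin) : Xin;
  cache.i.set_size(n, U); cache.f.set_size(n, U); cache.g.set_size(n, U);
  cache.o.set_size(n, U); cache.c.set_size(n, U); cache.h.set_size(n, U);
  cache.reverse = reverse;
  arma::rowvec hprev(U, arma::fill::zeros), cprev(U, arma::fill::zeros);
  for (int t = 0; t < n; ++t) {
    arma::rowvec a = X.row(t) * Wx + hprev * Wh + b;
    arma::rowvec ig = 1.0 / (1.0 + arma::exp(-a.cols(0, U - 1)));
    arma::rowvec fg = 1.0 / (1.0 + arma::exp(-a.cols(U, 2 * U - 1)));
    arma::rowvec gg = arma::tanh(a.cols(2 * U, 3 * U - 1));
    arma::rowvec og = 1.0 / (1.0 + arma::exp(-a.cols(3 * U, 4 * U - 1)));
    arma::rowvec ct = fg % cprev + ig % gg;
    arma::rowvec ht = og % arma::tanh(ct);
    cache.i.row(t) = ig; cache.f.row(t) = fg; cache.g.row(t) = gg;
    cache.o.row(t) = og; cache.c.row(t) = ct; cache.h.row(t) = ht;
    hprev = ht; cprev = ct;
  }
  return reverse ? arma::flipud(cache.h) : cache.h;
}

static void lstm_backward(const arma::mat& Xin, const arma::mat& Wx,
                          const arma::mat& Wh, const LSTMCache& cache,
                          const arma::mat& dHin, arma::mat& dX, arma::mat& dWx,
                          arma::mat& dWh, arma::rowvec& db) {
  const int n = Xin.n_rows, U = Wh.n_rows;
  arma::mat X = cache.reverse ? arma::flipud(Xin) : Xin;
  arma::mat dH = cache.reverse ? arma::flipud(dHin) : dHin;
  dWx.zeros(Wx.n_rows, Wx.n_cols);
  dWh.zeros(U, 4 * U);
  db.zeros(4 * U);
  arma::mat dXp(n, Xin.n_cols);
  arma::rowvec dh_next(U, arma::fill::zeros), dc_next(U, arma::fill::zeros);
  for (int t = n - 1; t >= 0; --t) {
    arma::rowvec dh = dH.row(t) + dh_next;
    arma::rowvec tc = arma::tanh(cache.c.row(t));
    arma::rowvec do_ = dh % tc;
    arma::rowvec dc = dc_next + dh % cache.o.row(t) % (1.0 - tc % tc);
    arma::rowvec cprev =
        (t > 0) ? cache.c.row(t - 1) : arma::rowvec(U, arma::fill::zeros);
    arma::rowvec di = dc % cache.g.row(t);
    arma::rowvec dg = dc % cache.i.row(t);
    arma::rowvec df = dc % cprev;
    dc_next = dc % cache.f.row(t);
    arma::rowvec da(4 * U);
    da.cols(0, U - 1) = di % cache.i.row(t) % (1.0 - cache.i.row(t));
    da.cols(U, 2 * U - 1) = df % cache.f.row(t) % (1.0 - cache.f.row(t));
    da.cols(2 * U, 3 * U - 1) = dg % (1.0 - cache.g.row(t) % cache.g.row(t));
    da.cols(3 * U, 4 * U - 1) = do_ % cache.o.row(t) % (1.0 - cache.o.row(t));
    dWx += X.row(t).t() * da;
    db += da;
    if (t > 0) {
      dWh += cache.h.row(t - 1).t() * da;
      dh_next = da * Wh.t();
    }
    dXp.row(t) = da * Wx.t();
  }
  dX = cache.reverse ? arma::flipud(dXp) : dXp;
}

// reshape T x F -> (T/R) x (F*R): row j = concat of base rows jR..jR+R-1
static arma::mat pool_reshape(const arma::mat& M, int R) {
  const int T = M.n_rows, F = M.n_cols, n = T / R;
  arma::mat out(n, F * R);
  for (int r = 0; r < R; ++r)
    for (int f = 0; f < F; ++f)
      for (int j = 0; j < n; ++j) out(j, r * F + f) = M(j * R + r, f);
  return out;
}

static arma::mat unpool_reshape(const arma::mat& M, int R, int F) {
  const int n = M.n_rows, T = n * R;
  arma::mat out(T, F);
  for (int r = 0; r < R; ++r)
    for (int f = 0; f < F; ++f)
      for (int j = 0; j < n; ++j) out(j * R + r, f) = M(j, r * F + f);
  return out;
}

struct NNCache {
  NNConfig cfg;
  arma::mat X;
  std::vector<arma::mat> conv_out;  // post-ReLU
  arma::mat Z0;                     // reshaped conv features
  std::vector<LSTMCache> lstm;      // 2 per layer (fwd, bwd)
  std::vector<arma::mat> lstm_in;   // input per layer
  arma::mat H;                      // final biLSTM output (post-dropout)
  arma::mat drop_mask;
  arma::mat Dn;                     // dense input
  arma::mat probs;                  // T x 15
};

static arma::mat nn_forward_impl(const NNConfig& c,
                                 std::vector<arma::mat>& P,
                                 const arma::mat& X, bool training,
                                 NNCache* cache) {
  const int T = X.n_rows;
  if (T % c.R != 0) stop("input length must be divisible by the reshape factor");
  int pi = 0;
  arma::mat cur = X;
  std::vector<arma::mat> conv_out;
  for (size_t l = 0; l < c.conv_filters.size(); ++l) {
    arma::mat W = P[pi++];
    arma::rowvec b = P[pi++].row(0);
    cur = conv1d_forward(cur, W, b, c.conv_width, c.conv_dilations[l]);
    cur.transform([](double v) { return v > 0 ? v : 0.0; });  // ReLU
    conv_out.push_back(cur);
  }
  arma::mat Z0 = pool_reshape(cur, c.R);

  std::vector<LSTMCache> lcaches(2 * c.layers);
  std::vector<arma::mat> lstm_in;
  arma::mat lin = Z0;
  arma::mat H;
  for (int l = 0; l < c.layers; ++l) {
    lstm_in.push_back(lin);
    arma::mat Wxf = P[pi++], Whf = P[pi++];
    arma::rowvec bf = P[pi++].row(0);
    arma::mat Wxb = P[pi++], Whb = P[pi++];
    arma::rowvec bb = P[pi++].row(0);
    arma::mat hf = lstm_forward(lin, Wxf, Whf, bf, false, lcaches[2 * l]);
    arma::mat hb = lstm_forward(lin, Wxb, Whb, bb, true, lcaches[2 * l + 1]);
    H = arma::join_rows(hf, hb);
    lin = H;
  }

  arma::mat drop_mask;
  if (training && c.dropout > 0) {
    drop_mask.set_size(H.n_rows, H.n_cols);
    GetRNGstate();
    for (arma::uword k = 0; k < drop_mask.n_elem; ++k)
      drop_mask(k) = (unif_rand() >= c.dropout) ? 1.0 / (1.0 - c.dropout) : 0.0;
    PutRNGstate();
    H = H % drop_mask;
  }

  arma::mat Dn = c.residual ? arma::join_rows(H, Z0) : H;
  arma::mat Wd = P[pi++];
  arma::rowvec bd = P[pi++].row(0);
  arma::mat logits = Dn * Wd;
  logits.each_row() += bd;  // n x 15R
  arma::mat logitsT = unpool_reshape(logits, c.R, 15);

  // row softmax
  arma::mat probs(T, 15);
  for (int t = 0; t < T; ++t) {
    arma::rowvec r = logitsT.row(t);
    r -= r.max();
    r = arma::exp(r);
    probs.row(t) = r / arma::accu(r);
  }

  if (cache) {
    cache->cfg = c;
    cache->X = X;
    cache->conv_out = conv_out;
    cache->Z0 = Z0;
    cache->lstm = lcaches;
    cache->lstm_in = lstm_in;
    cache->H = H;
    cache->drop_mask = drop_mask;
    cache->Dn = Dn;
    cache->probs = probs;
  }
  return probs;
}

// [[Rcpp::export]]
SEXP cpp_nn_forward(NumericVector par, const List& cfg, const arma::mat& X,
                    bool training, bool keep_cache) {
  NNConfig c = parse_cfg(cfg);
  std::vector<Shape> shapes = param_shapes(c);
  if (par.size() != (int)total_params(shapes))
    stop("parameter vector has wrong length");
  std::vector<arma::mat> P = param_views(REAL(par), shapes);
  if (!keep_cache) {
    arma::mat probs = nn_forward_impl(c, P, X, training, nullptr);
    return wrap(probs);
  }
  NNCache* cache = new NNCache();
  arma::mat probs = nn_forward_impl(c, P, X, training, cache);
  XPtr<NNCache> ptr(cache, true);
  return List::create(_["probs"] = probs, _["cache"] = ptr);
}

// [[Rcpp::export]]
NumericVector cpp_nn_backward(NumericVector par, const List& cfg, SEXP cacheSEXP,
                              const arma::mat& dprobs) {
  NNConfig c = parse_cfg(cfg);
  std::vector<Shape> shapes = param_shapes(c);
  std::vector<arma::mat> P = param_views(REAL(par), shapes);
  XPtr<NNCache> cache(cacheSEXP);
  const arma::mat& probs = cache->probs;
  const int T = probs.n_rows;

  NumericVector grad((int)total_params(shapes));
  std::vector<arma::mat> G = param_views(REAL(grad), shapes);

  // softmax backward
  arma::mat dlogitsT(T, 15);
  for (int t = 0; t < T; ++t) {
    double dot = arma::accu(dprobs.row(t) % probs.row(t));
    dlogitsT.row(t) = probs.row(t) % (dprobs.row(t) - dot);
  }
  arma::mat dlogits = pool_reshape(dlogitsT, c.R);  // n x 15R

  // dense backward
  int pi_dense = (int)shapes.size() - 2;
  const arma::mat& Wd = P[pi_dense];
  G[pi_dense] = cache->Dn.t() * dlogits;
  G[pi_dense + 1].row(0) = arma::sum(dlogits, 0);
  arma::mat dDn = dlogits * Wd.t();

  const int twoU = 2 * c.U;
  arma::mat dH = dDn.cols(0, twoU - 1);
  arma::mat dZ0(cache->Z0.n_rows, cache->Z0.n_cols, arma::fill::zeros);
  if (c.residual) dZ0 += dDn.cols(twoU, dDn.n_cols - 1);

  if (cache->drop_mask.n_elem > 0) dH = dH % cache->drop_mask;

  // LSTM layers, top down
  int pi = (int)c.conv_filters.size() * 2;  // first lstm param index
  for (int l = c.layers - 1; l >= 0; --l) {
    int base = pi + 6 * l;
    const arma::mat& lin = cache->lstm_in[l];
    arma::mat dXf, dXb, dWx, dWh;
    arma::rowvec db;
    lstm_backward(lin, P[base], P[base + 1], cache->lstm[2 * l],
                  dH.cols(0, c.U - 1), dXf, dWx, dWh, db);
    G[base] = dWx; G[base + 1] = dWh; G[base + 2].row(0) = db;
    lstm_backward(lin, P[base + 3], P[base + 4], cache->lstm[2 * l + 1],
                  dH.cols(c.U, twoU - 1), dXb, dWx, dWh, db);
    G[base + 3] = dWx; G[base + 4] = dWh; G[base + 5].row(0) = db;
    arma::mat dlin = dXf + dXb;
    if (l == 0) dZ0 += dlin; else dH = dlin;
  }

  // reshape back to per-base conv gradient
  arma::mat dconv = unpool_reshape(dZ0, c.R, c.conv_filters.back());

  // conv stack backward
  for (int l = (int)c.conv_filters.size() - 1; l >= 0; --l) {
    const arma::mat& out = cache->conv_out[l];
    dconv = dconv % arma::conv_to<arma::mat>::from(out > 0);  // ReLU
    const arma::mat& in = (l == 0) ? cache->X : cache->conv_out[l - 1];
    arma::mat dX, dW;
    arma::rowvec db;
    conv1d_backward(in, P[2 * l], c.conv_width, c.conv_dilations[l], dconv,
                    dX, dW, db, l > 0);
    G[2 * l] = dW;
    G[2 * l + 1].row(0) = db;
    if (l > 0) dconv = dX;
  }
  return grad;
}
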