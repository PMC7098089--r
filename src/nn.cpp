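// Compiled compute core: dilated-CNN and BiLSTM sequence trunks, dense heads,
// batch normalization, dropout, RMSprop, and full backpropagation.
// Single precision throughout; all randomness comes from one mt19937 stream
// seeded from R so that training is reproducible on a fixed thread policy.
#include <RcppArmadillo.h>
#include <random>
#include <map>
#include <string>
#include <cstring>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::fcube;
using arma::uword;

// ------------------------------------------------------------------ utilities

struct RNG {
  std::mt19937 g;
  explicit RNG(uint32_t seed) : g(seed) {}
  inline float u01() { return (g() >> 8) * (1.0f / 16777216.0f); }
  // inverted-dropout mask: entries are 1/(1-p) with prob 1-p, else 0
  fmat dropout_mask(uword r, uword c, float p) {
    fmat m(r, c);
    const float keep = 1.0f - p, scale = 1.0f / keep;
    float* ptr = m.memptr();
    for (uword i = 0; i < r * c; ++i) ptr[i] = (u01() < keep) ? scale : 0.0f;
    return m;
  }
  // draw a mask into `mask` and apply it to X in the same pass
  void apply_dropout(fmat& X, fmat& mask, float p) {
    mask.set_size(X.n_rows, X.n_cols);
    const float keep = 1.0f - p, scale = 1.0f / keep;
    float* x = X.memptr();
    float* m = mask.memptr();
    for (uword i = 0; i < X.n_elem; ++i) {
      if (u01() < keep) { m[i] = scale; x[i] *= scale; }
      else { m[i] = 0.0f; x[i] = 0.0f; }
    }
  }
  std::vector<uword> permutation(uword n) {
    std::vector<uword> idx(n);
    for (uword i = 0; i < n; ++i) idx[i] = i;
    std::shuffle(idx.begin(), idx.end(), g);
    return idx;
  }
};

static inline fmat lrelu(const fmat& x, float a) {
  fmat y = x;
  float* p = y.memptr();
  for (uword i = 0; i < y.n_elem; ++i) if (p[i] < 0.0f) p[i] *= a;
  return y;
}
static inline void lrelu_inplace(fmat& x, float a) {
  float* p = x.memptr();
  for (uword i = 0; i < x.n_elem; ++i) if (p[i] < 0.0f) p[i] *= a;
}
// gradient from the (monotone, sign-preserving) activation value
static inline fmat lrelu_grad(const fmat& act, float a) {
  fmat g(act.n_rows, act.n_cols);
  const float* p = act.memptr();
  float* q = g.memptr();
  for (uword i = 0; i < g.n_elem; ++i) q[i] = p[i] > 0.0f ? 1.0f : a;
  return g;
}
// d *= lrelu'(act), one fused pass
static inline void lrelu_bwd_inplace(fmat& d, const fmat& act, float a) {
  float* p = d.memptr();
  const float* q = act.memptr();
  for (uword i = 0; i < d.n_elem; ++i) if (q[i] <= 0.0f) p[i] *= a;
}
static inline fmat sigmoid(const fmat& x) { return 1.0f / (1.0f + arma::exp(-x)); }
// contiguous column-wise bias add (each_row() is strided in column-major)
static inline void add_bias(fmat& X, const fvec& b) {
  for (uword c = 0; c < X.n_cols; ++c) {
    float* x = X.colptr(c);
    const float bc = b(c);
    for (uword i = 0; i < X.n_rows; ++i) x[i] += bc;
  }
}

static fmat as_fmat(SEXP s) {
  NumericMatrix m(s);
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = (float)m(i, j);
  return out;
}
static fvec as_fvec(SEXP s) {
  NumericVector v(s);
  fvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out(i) = (float)v[i];
  return out;
}
static NumericMatrix wrap_fmat(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) out(i, j) = m(i, j);
  return out;
}
static NumericVector wrap_fvec(const fvec& v) {
  NumericVector out(v.n_elem);
  for (uword i = 0; i < v.n_elem; ++i) out[i] = v(i);
  return out;
}

// --------------------------------------------------------------- batch norm

struct BNState {
  fmat xhat;     // N x C
  fvec invstd;   // C
};

// training-mode forward; updates running stats in place.
// contiguous column passes (channels are columns)
static fmat bn_forward_train(const fmat& X, const fvec& g, const fvec& be,
                             fvec& rm, fvec& rv, float mom, float eps,
                             BNState& st) {
  const uword N = X.n_rows, C = X.n_cols;
  st.xhat.set_size(N, C);
  st.invstd.set_size(C);
  fmat Y(N, C);
  for (uword c = 0; c < C; ++c) {
    const float* x = X.colptr(c);
    double s = 0;
    for (uword i = 0; i < N; ++i) s += x[i];
    const float mu = (float)(s / N);
    double s2 = 0;
    for (uword i = 0; i < N; ++i) { const float d = x[i] - mu; s2 += (double)d * d; }
    const float var = (float)(s2 / N);
    const float is = 1.0f / std::sqrt(var + eps);
    st.invstd(c) = is;
    const float gc = g(c), bc = be(c);
    float* xh = st.xhat.colptr(c);
    float* y = Y.colptr(c);
    for (uword i = 0; i < N; ++i) {
      const float v = (x[i] - mu) * is;
      xh[i] = v;
      y[i] = gc * v + bc;
    }
    rm(c) = mom * rm(c) + (1.0f - mom) * mu;
    rv(c) = mom * rv(c) +
            (1.0f - mom) * var * (N > 1 ? (float)N / (N - 1) : 1.0f);
  }
  return Y;
}

static fmat bn_forward_eval(const fmat& X, const fvec& g, const fvec& be,
                            const fvec& rm, const fvec& rv, float eps) {
  const uword N = X.n_rows, C = X.n_cols;
  fmat Y(N, C);
  for (uword c = 0; c < C; ++c) {
    const float is = 1.0f / std::sqrt(rv(c) + eps);
    const float a = g(c) * is, b = be(c) - g(c) * is * rm(c);
    const float* x = X.colptr(c);
    float* y = Y.colptr(c);
    for (uword i = 0; i < N; ++i) y[i] = a * x[i] + b;
  }
  return Y;
}

static fmat bn_backward(const fmat& dY, const fvec& g, const BNState& st,
                        fvec& dg, fvec& dbe) {
  const uword N = dY.n_rows, C = dY.n_cols;
  dg.set_size(C);
  dbe.set_size(C);
  fmat dX(N, C);
  for (uword c = 0; c < C; ++c) {
    const float* dy = dY.colptr(c);
    const float* xh = st.xhat.colptr(c);
    double sdy = 0, sdyx = 0;
    for (uword i = 0; i < N; ++i) { sdy += dy[i]; sdyx += (double)dy[i] * xh[i]; }
    dg(c) = (float)sdyx;
    dbe(c) = (float)sdy;
    const float mdy = (float)(sdy / N), mdyx = (float)(sdyx / N);
    const float k = g(c) * st.invstd(c);
    float* dx = dX.colptr(c);
    for (uword i = 0; i < N; ++i)
      dx[i] = k * (dy[i] - mdy - xh[i] * mdyx);
  }
  return dX;
}

// ---------------------------------------------------------------- CNN trunk


struct CnnParams {
  fmat W1;                 // (K1*5) x F1
  fvec b1, g1, be1, rm1, rv1;
  std::vector<fmat> Wd;    // 3 x [(K2*F1) x F2]
  std::vector<fvec> bd;
  fvec g2, be2, rm2, rv2;
  int K1 = 17, K2 = 5;
  std::vector<int> dil{1, 3, 7};
  int F1() const { return (int)W1.n_cols; }
  int F2() const { return (int)Wd[0].n_cols; }
  int Cout() const { return 3 * F2(); }
};

static CnnParams cnn_load(List p) {
  CnnParams P;
  P.W1 = as_fmat(p["W1"]); P.b1 = as_fvec(p["b1"]);
  P.g1 = as_fvec(p["g1"]); P.be1 = as_fvec(p["be1"]);
  P.rm1 = as_fvec(p["rm1"]); P.rv1 = as_fvec(p["rv1"]);
  List wd = p["Wd"], bd = p["bd"];
  for (int j = 0; j < 3; ++j) {
    P.Wd.push_back(as_fmat(wd[j]));
    P.bd.push_back(as_fvec(bd[j]));
  }
  P.g2 = as_fvec(p["g2"]); P.be2 = as_fvec(p["be2"]);
  P.rm2 = as_fvec(p["rm2"]); P.rv2 = as_fvec(p["rv2"]);
  return P;
}
static List cnn_dump(const CnnParams& P) {
  return List::create(
    _["W1"] = wrap_fmat(P.W1), _["b1"] = wrap_fvec(P.b1),
    _["g1"] = wrap_fvec(P.g1), _["be1"] = wrap_fvec(P.be1),
    _["rm1"] = wrap_fvec(P.rm1), _["rv1"] = wrap_fvec(P.rv1),
    _["Wd"] = List::create(wrap_fmat(P.Wd[0]), wrap_fmat(P.Wd[1]), wrap_fmat(P.Wd[2])),
    _["bd"] = List::create(wrap_fvec(P.bd[0]), wrap_fvec(P.bd[1]), wrap_fvec(P.bd[2])),
    _["g2"] = wrap_fvec(P.g2), _["be2"] = wrap_fvec(P.be2),
    _["rm2"] = wrap_fvec(P.rm2), _["rv2"] = wrap_fvec(P.rv2));
}

struct CnnCache {
  fmat M1;                  // one-hot patch matrix (B*L) x (K1*5)
  int B = 0, L = 0;
  fmat A1;                  // (B*L) x F1 ; post-BN/activation/dropout
  BNState bn1, bn2;
  fmat D1;                  // dropout mask on A1
  fmat A2act;               // (B*L) x 3F2 activation after the dilated block
  arma::umat argmax;        // B x 3F2 (position of max)
  fmat Dp;                  // dropout mask on pooled
  std::vector<fmat> M2;     // im2col inputs per dilation
};

// first convolution via a one-hot im2col: M1 is the 0/1 patch matrix, so
// forward and weight gradients are single GEMMs
static void conv1_im2col(const arma::imat& codes, int K, fmat& M1) {
  const int B = codes.n_rows, L = codes.n_cols, half = K / 2;
  M1.zeros((uword)B * L, (uword)K * 5);
  for (int k = 0; k < K; ++k) {
    const int off = k - half;
    for (int b = 0; b < B; ++b) {
      const uword base = (uword)b * L;
      const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
      for (int t = t0; t < t1; ++t)
        M1(base + t, (uword)k * 5 + (codes(b, t + off) - 1)) = 1.0f;
    }
  }
}

// column-contiguous im2col for the dilated convolutions:
// A: (B*L) x C ; M: (B*L) x (K*C); destination column k*C+c is source
// column c shifted by (k-half)*d within each sample
static void im2col_dil(const fmat& A, int B, int L, int K, int d, fmat& M) {
  const int C = A.n_cols, half = K / 2;
  M.zeros((uword)B * L, (uword)K * C);
  for (int k = 0; k < K; ++k) {
    const int off = (k - half) * d;
    const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
    if (t0 >= t1) continue;
    for (int c = 0; c < C; ++c) {
      const float* src = A.colptr(c);
      float* dst = M.colptr((uword)k * C + c);
      for (int b = 0; b < B; ++b) {
        const uword base = (uword)b * L;
        std::memcpy(dst + base + t0, src + base + t0 + off,
                    sizeof(float) * (t1 - t0));
      }
    }
  }
}

static void col2im_dil(const fmat& dM, int B, int L, int K, int d, fmat& dA) {
  const int C = dM.n_cols / K, half = K / 2;
  for (int k = 0; k < K; ++k) {
    const int off = (k - half) * d;
    const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
    if (t0 >= t1) continue;
    for (int c = 0; c < C; ++c) {
      const float* src = dM.colptr((uword)k * C + c);
      float* dst = dA.colptr(c);
      for (int b = 0; b < B; ++b) {
        const uword base = (uword)b * L;
        const float* s = src + base + t0;
        float* p = dst + base + t0 + off;
        for (int t = 0; t < t1 - t0; ++t) p[t] += s[t];
      }
    }
  }
}

static fmat cnn_forward(CnnParams& P, const arma::imat& codes, bool training,
                        float leaky, float drop, float bn_mom, float bn_eps,
                        RNG* rng, CnnCache* C, fmat* featmaps_out = nullptr) {
  const int B = codes.n_rows, L = codes.n_cols;
  fmat M1;
  conv1_im2col(codes, P.K1, M1);
  fmat Z1 = M1 * P.W1;
  add_bias(Z1, P.b1);
  BNState bn1;
  fmat A1;
  if (training) A1 = bn_forward_train(Z1, P.g1, P.be1, P.rm1, P.rv1, bn_mom, bn_eps, bn1);
  else A1 = bn_forward_eval(Z1, P.g1, P.be1, P.rm1, P.rv1, bn_eps);
  Z1.reset();
  lrelu_inplace(A1, leaky);
  fmat D1;
  if (training) rng->apply_dropout(A1, D1, drop);

  fmat Z2((uword)B * L, P.Cout());
  std::vector<fmat> M2loc;
  std::vector<fmat>* M2p;
  if (C) { C->M2.resize(3); M2p = &C->M2; }
  else { M2loc.resize(3); M2p = &M2loc; }
  std::vector<fmat>& M2 = *M2p;
  for (int j = 0; j < 3; ++j) {
    im2col_dil(A1, B, L, P.K2, P.dil[j], M2[j]);
    fmat Zj = M2[j] * P.Wd[j];
    add_bias(Zj, P.bd[j]);
    Z2.cols((uword)j * P.F2(), (uword)(j + 1) * P.F2() - 1) = Zj;
  }
  BNState bn2;
  fmat A2;
  if (training) A2 = bn_forward_train(Z2, P.g2, P.be2, P.rm2, P.rv2, bn_mom, bn_eps, bn2);
  else A2 = bn_forward_eval(Z2, P.g2, P.be2, P.rm2, P.rv2, bn_eps);
  Z2.reset();
  lrelu_inplace(A2, leaky);
  if (featmaps_out) *featmaps_out = A2;

  fmat pooled(B, P.Cout());
  arma::umat amax(B, P.Cout());
  for (int b = 0; b < B; ++b) {
    const uword base = (uword)b * L;
    for (int c = 0; c < P.Cout(); ++c) {
      uword best = base;
      float bv = A2(base, c);
      for (int t = 1; t < L; ++t)
        if (A2(base + t, c) > bv) { bv = A2(base + t, c); best = base + t; }
      pooled(b, c) = bv;
      amax(b, c) = best;
    }
  }
  fmat Dp;
  if (training) rng->apply_dropout(pooled, Dp, drop);

  if (C) {
    C->M1 = std::move(M1); C->B = B; C->L = L;
    C->bn1 = std::move(bn1);
    C->D1 = std::move(D1); C->A1 = std::move(A1);
    C->bn2 = std::move(bn2); C->A2act = std::move(A2);
    C->argmax = std::move(amax); C->Dp = std::move(Dp);
  }
  return pooled;
}

struct CnnGrads {
  fmat dW1; fvec db1, dg1, dbe1;
  std::vector<fmat> dWd; std::vector<fvec> dbd;
  fvec dg2, dbe2;
};

static void cnn_backward(const CnnParams& P, CnnCache& C, const fmat& dpooled_in,
                         float leaky, CnnGrads& G) {
  const int B = C.B, L = C.L;
  fmat dpooled = dpooled_in;
  if (C.Dp.n_elem) dpooled %= C.Dp;
  fmat dA2((uword)B * L, P.Cout(), arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < P.Cout(); ++c)
      dA2(C.argmax(b, c), c) += dpooled(b, c);
  lrelu_bwd_inplace(dA2, C.A2act, leaky);
  fmat dZ2 = bn_backward(dA2, P.g2, C.bn2, G.dg2, G.dbe2);
  dA2.reset();

  fmat dA1(C.A1.n_rows, C.A1.n_cols, arma::fill::zeros);
  G.dWd.resize(3); G.dbd.resize(3);
  for (int j = 0; j < 3; ++j) {
    fmat dZj = dZ2.cols((uword)j * P.F2(), (uword)(j + 1) * P.F2() - 1);
    G.dWd[j] = C.M2[j].t() * dZj;
    G.dbd[j] = arma::sum(dZj, 0).t();
    fmat dMj = dZj * P.Wd[j].t();
    col2im_dil(dMj, B, L, P.K2, P.dil[j], dA1);
  }
  if (C.D1.n_elem) dA1 %= C.D1;
  // the activation's sign determines the leaky-ReLU gradient; dropped
  // positions are already zeroed by the mask
  lrelu_bwd_inplace(dA1, C.A1, leaky);
  fmat dZ1 = bn_backward(dA1, P.g1, C.bn1, G.dg1, G.dbe1);
  G.dW1 = C.M1.t() * dZ1;
  G.db1 = arma::sum(dZ1, 0).t();
}

// --------------------------------------------------------------- RNN trunk

struct RnnParams {
  fmat W1f, W1b, W2f, W2b;  // (C+U) x 4U
  fvec b1f, b1b, b2f, b2b;
  fmat Wtd;                 // 2U x D
  fvec btd;
  int U() const { return (int)W1f.n_cols / 4; }
  int D() const { return (int)Wtd.n_cols; }
};

static RnnParams rnn_load(List p) {
  RnnParams P;
  P.W1f = as_fmat(p["W1f"]); P.b1f = as_fvec(p["b1f"]);
  P.W1b = as_fmat(p["W1b"]); P.b1b = as_fvec(p["b1b"]);
  P.W2f = as_fmat(p["W2f"]); P.b2f = as_fvec(p["b2f"]);
  P.W2b = as_fmat(p["W2b"]); P.b2b = as_fvec(p["b2b"]);
  P.Wtd = as_fmat(p["Wtd"]); P.btd = as_fvec(p["btd"]);
  return P;
}
static List rnn_dump(const RnnParams& P) {
  return List::create(
    _["W1f"] = wrap_fmat(P.W1f), _["b1f"] = wrap_fvec(P.b1f),
    _["W1b"] = wrap_fmat(P.W1b), _["b1b"] = wrap_fvec(P.b1b),
    _["W2f"] = wrap_fmat(P.W2f), _["b2f"] = wrap_fvec(P.b2f),
    _["W2b"] = wrap_fmat(P.W2b), _["b2b"] = wrap_fvec(P.b2b),
    _["Wtd"] = wrap_fmat(P.Wtd), _["btd"] = wrap_fvec(P.btd));
}

struct LstmCache {
  fcube In;               // B x (C+U) x T   cell input [x_t, h_prev]
  fcube I, F, O, G, Cc, Tc; // gate activations, cell state, tanh(cell)
};

static void lstm_dir_forward(const fmat& W, const fvec& b, const fcube& X,
                             bool forward, LstmCache* cache, fcube& H) {
  const int B = X.n_rows, C = X.n_cols, T = X.n_slices;
  const int U = (int)W.n_cols / 4;
  H.set_size(B, U, T);
  if (cache) {
    cache->In.set_size(B, C + U, T);
    cache->I.set_size(B, U, T); cache->F.set_size(B, U, T);
    cache->O.set_size(B, U, T); cache->G.set_size(B, U, T);
    cache->Cc.set_size(B, U, T); cache->Tc.set_size(B, U, T);
  }
  fmat h(B, U, arma::fill::zeros), c(B, U, arma::fill::zeros);
  for (int s = 0; s < T; ++s) {
    const int t = forward ? s : T - 1 - s;
    fmat In = arma::join_rows(fmat(X.slice(t)), h);
    fmat Z = In * W;
    add_bias(Z, b);
    fmat i = sigmoid(Z.cols(0, U - 1));
    fmat f = sigmoid(Z.cols(U, 2 * U - 1));
    fmat o = sigmoid(Z.cols(2 * U, 3 * U - 1));
    fmat g = arma::tanh(Z.cols(3 * U, 4 * U - 1));
    c = f % c + i % g;
    fmat tc = arma::tanh(c);
    h = o % tc;
    H.slice(t) = h;
    if (cache) {
      cache->In.slice(t) = In;
      cache->I.slice(t) = i; cache->F.slice(t) = f;
      cache->O.slice(t) = o; cache->G.slice(t) = g;
      cache->Cc.slice(t) = c; cache->Tc.slice(t) = tc;
    }
  }
}

static void lstm_dir_backward(const fmat& W, const LstmCache& C, const fcube& dH,
                              bool forward, fmat& dW, fvec& db, fcube* dX) {
  const int B = dH.n_rows, U = dH.n_cols, T = dH.n_slices;
  const int Cin = (int)C.In.n_cols - U;
  dW.zeros(W.n_rows, W.n_cols);
  db.zeros(W.n_cols);
  fmat dh_next(B, U, arma::fill::zeros), dc_next(B, U, arma::fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    const int t = forward ? s : T - 1 - s;
    const int tprev = forward ? t - 1 : t + 1;
    fmat dh = fmat(dH.slice(t)) + dh_next;
    const fmat &i = C.I.slice(t), &f = C.F.slice(t), &o = C.O.slice(t),
               &g = C.G.slice(t), &tc = C.Tc.slice(t);
    fmat cprev = (s == 0) ? fmat(B, U, arma::fill::zeros) : fmat(C.Cc.slice(tprev));
    fmat dc = dc_next + dh % o % (1.0f - tc % tc);
    fmat dZ(B, 4 * U);
    dZ.cols(0, U - 1) = dc % g % i % (1.0f - i);
    dZ.cols(U, 2 * U - 1) = dc % cprev % f % (1.0f - f);
    dZ.cols(2 * U, 3 * U - 1) = dh % tc % o % (1.0f - o);
    dZ.cols(3 * U, 4 * U - 1) = dc % i % (1.0f - g % g);
    dW += fmat(C.In.slice(t)).t() * dZ;
    db += arma::sum(dZ, 0).t();
    fmat dIn = dZ * W.t();
    if (dX) dX->slice(t) += dIn.cols(0, Cin - 1);
    dh_next = dIn.cols(Cin, Cin + U - 1);
    dc_next = dc % f;
  }
}

struct RnnCache {
  fcube X1;                  // one-hot input B x 5 x T
  LstmCache c1f, c1b, c2f, c2b;
  fcube H1d, H2d;            // post-dropout layer outputs B x 2U x T
  fcube D1, D2;              // dropout masks
};

static fmat rnn_forward(RnnParams& P, const arma::imat& codes, int t0, int T,
                        bool training, float drop, RNG* rng, RnnCache* C) {
  const int B = codes.n_rows, U = P.U(), D = P.D();
  fcube X1(B, 5, T, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t)
      X1(b, codes(b, t0 + t) - 1, t) = 1.0f;

  fcube H1f, H1b;
  lstm_dir_forward(P.W1f, P.b1f, X1, true, C ? &C->c1f : nullptr, H1f);
  lstm_dir_forward(P.W1b, P.b1b, X1, false, C ? &C->c1b : nullptr, H1b);
  fcube H1(B, 2 * U, T);
  for (int t = 0; t < T; ++t)
    H1.slice(t) = arma::join_rows(fmat(H1f.slice(t)), fmat(H1b.slice(t)));
  fcube D1;
  if (training) {
    D1.set_size(B, 2 * U, T);
    for (int t = 0; t < T; ++t) D1.slice(t) = rng->dropout_mask(B, 2 * U, drop);
    H1 %= D1;
  }
  fcube H2f, H2b;
  lstm_dir_forward(P.W2f, P.b2f, H1, true, C ? &C->c2f : nullptr, H2f);
  lstm_dir_forward(P.W2b, P.b2b, H1, false, C ? &C->c2b : nullptr, H2b);
  fcube H2(B, 2 * U, T);
  for (int t = 0; t < T; ++t)
    H2.slice(t) = arma::join_rows(fmat(H2f.slice(t)), fmat(H2b.slice(t)));
  fcube D2;
  if (training) {
    D2.set_size(B, 2 * U, T);
    for (int t = 0; t < T; ++t) D2.slice(t) = rng->dropout_mask(B, 2 * U, drop);
    H2 %= D2;
  }
  // time-distributed linear map, flattened time-major
  fmat feat(B, (uword)T * D);
  for (int t = 0; t < T; ++t) {
    fmat out = fmat(H2.slice(t)) * P.Wtd;
    add_bias(out, P.btd);
    feat.cols((uword)t * D, (uword)(t + 1) * D - 1) = out;
  }
  if (C) {
    C->X1 = std::move(X1); C->H1d = std::move(H1); C->H2d = std::move(H2);
    C->D1 = std::move(D1); C->D2 = std::move(D2);
  }
  return feat;
}

struct RnnGrads {
  fmat dW1f, dW1b, dW2f, dW2b, dWtd;
  fvec db1f, db1b, db2f, db2b, dbtd;
};

static void rnn_backward(const RnnParams& P, RnnCache& C, const fmat& dfeat,
                         RnnGrads& G) {
  const int B = C.H2d.n_rows, U = P.U(), D = P.D(), T = C.H2d.n_slices;
  G.dWtd.zeros(P.Wtd.n_rows, P.Wtd.n_cols);
  G.dbtd.zeros(P.btd.n_elem);
  fcube dH2(B, 2 * U, T);
  for (int t = 0; t < T; ++t) {
    fmat dOut = dfeat.cols((uword)t * D, (uword)(t + 1) * D - 1);
    G.dWtd += fmat(C.H2d.slice(t)).t() * dOut;
    G.dbtd += arma::sum(dOut, 0).t();
    dH2.slice(t) = dOut * P.Wtd.t();
  }
  if (C.D2.n_elem) dH2 %= C.D2;
  fcube dH2f = dH2.cols(0, U - 1), dH2b = dH2.cols(U, 2 * U - 1);
  fcube dH1(B, 2 * U, T, arma::fill::zeros);
  lstm_dir_backward(P.W2f, C.c2f, dH2f, true, G.dW2f, G.db2f, &dH1);
  lstm_dir_backward(P.W2b, C.c2b, dH2b, false, G.dW2b, G.db2b, &dH1);
  if (C.D1.n_elem) dH1 %= C.D1;
  fcube dH1f = dH1.cols(0, U - 1), dH1b = dH1.cols(U, 2 * U - 1);
  lstm_dir_backward(P.W1f, C.c1f, dH1f, true, G.dW1f, G.db1f, nullptr);
  lstm_dir_backward(P.W1b, C.c1b, dH1b, false, G.dW1b, G.db1b, nullptr);
}

// -------------------------------------------------------------- dense head

struct HeadParams {
  std::vector<fmat> W;
  std::vector<fvec> b;
};
static HeadParams head_load(List p) {
  HeadParams H;
  List w = p["W"], b = p["b"];
  for (int j = 0; j < w.size(); ++j) {
    H.W.push_back(as_fmat(w[j]));
    H.b.push_back(as_fvec(b[j]));
  }
  return H;
}
static List head_dump(const HeadParams& H) {
  List w(H.W.size()), b(H.b.size());
  for (size_t j = 0; j < H.W.size(); ++j) { w[j] = wrap_fmat(H.W[j]); b[j] = wrap_fvec(H.b[j]); }
  return List::create(_["W"] = w, _["b"] = b);
}

struct HeadCache { std::vector<fmat> A; std::vector<fmat> Z; };

static fmat head_forward(const HeadParams& H, const fmat& X, float leaky,
                         HeadCache* C) {
  fmat A = X;
  if (C) { C->A.clear(); C->Z.clear(); }
  const size_t nl = H.W.size();
  for (size_t j = 0; j < nl; ++j) {
    if (C) C->A.push_back(A);
    fmat Z = A * H.W[j];
    add_bias(Z, H.b[j]);
    if (j + 1 < nl) {
      if (C) C->Z.push_back(Z);
      A = lrelu(Z, leaky);
    } else {
      A = Z;  // logits
    }
  }
  return A;
}

struct HeadGrads { std::vector<fmat> dW; std::vector<fvec> db; };

static fmat head_backward(const HeadParams& H, const HeadCache& C,
                          const fmat& dlogit, float leaky, HeadGrads& G) {
  const size_t nl = H.W.size();
  G.dW.resize(nl); G.db.resize(nl);
  fmat d = dlogit;
  for (int j = (int)nl - 1; j >= 0; --j) {
    G.dW[j] = C.A[j].t() * d;
    G.db[j] = arma::sum(d, 0).t();
    d = d * H.W[j].t();
    if (j > 0) d %= lrelu_grad(C.Z[j - 1], leaky);
  }
  return d;  // gradient w.r.t. head input
}

// ---------------------------------------------------------------- RMSprop

struct RmsState { std::map<std::string, fmat> v; };

static void rms_update(RmsState& S, const std::string& key, fmat& theta,
                       const fmat& grad, float lr, float rho, float eps) {
  fmat& v = S.v[key];
  if (v.n_elem == 0) v.zeros(theta.n_rows, theta.n_cols);
  v = rho * v + (1.0f - rho) * (grad % grad);
  theta -= lr * grad / (arma::sqrt(v) + eps);
}
static void rms_update(RmsState& S, const std::string& key, fvec& theta,
                       const fvec& grad, float lr, float rho, float eps) {
  fmat th(theta.n_elem, 1), gr(grad.n_elem, 1);
  th.col(0) = theta; gr.col(0) = grad;
  rms_update(S, key, th, gr, lr, rho, eps);
  theta = th.col(0);
}

// ------------------------------------------------------ model-level driving

struct Opts {
  int epochs, batch, patience, rnn_window;
  float lr, rho, eps, leaky, drop_cnn, drop_rnn, drop_head, bn_mom, bn_eps;
  uint32_t seed;
  bool use_cnn, use_rnn, train_trunks, verbose;
};

static Opts parse_opts(List o) {
  Opts p;
  p.epochs = as<int>(o["epochs"]); p.batch = as<int>(o["batch"]);
  p.patience = as<int>(o["patience"]); p.rnn_window = as<int>(o["rnn_window"]);
  p.lr = (float)as<double>(o["lr"]); p.rho = (float)as<double>(o["rho"]);
  p.eps = (float)as<double>(o["eps"]); p.leaky = (float)as<double>(o["leaky"]);
  p.drop_cnn = (float)as<double>(o["drop_cnn"]);
  p.drop_rnn = (float)as<double>(o["drop_rnn"]);
  p.drop_head = o.containsElementNamed("drop_head")
                  ? (float)as<double>(o["drop_head"]) : 0.0f;
  p.bn_mom = (float)as<double>(o["bn_mom"]); p.bn_eps = (float)as<double>(o["bn_eps"]);
  p.seed = (uint32_t)as<double>(o["seed"]);
  p.use_cnn = as<bool>(o["use_cnn"]); p.use_rnn = as<bool>(o["use_rnn"]);
  p.train_trunks = as<bool>(o["train_trunks"]);
  p.verbose = as<bool>(o["verbose"]);
  return p;
}

// average precision with tied scores sharing one threshold block
static double ap_blocked(const std::vector<double>& y, const std::vector<double>& s) {
  const size_t n = y.size();
  std::vector<size_t> idx(n);
  for (size_t i = 0; i < n; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](size_t a, size_t b) { return s[a] > s[b]; });
  double P = 0;
  for (size_t i = 0; i < n; ++i) P += y[i];
  if (P == 0) return NA_REAL;
  double tp = 0, fp = 0, ap = 0, rprev = 0;
  size_t i = 0;
  while (i < n) {
    size_t j = i;
    double btp = 0, bfp = 0;
    while (j < n && s[idx[j]] == s[idx[i]]) {
      if (y[idx[j]] > 0) btp += 1; else bfp += 1;
      ++j;
    }
    tp += btp; fp += bfp;
    double rec = tp / P, prec = tp / (tp + fp);
    ap += (rec - rprev) * prec;
    rprev = rec;
    i = j;
  }
  return ap;
}

struct SeqModel {
  CnnParams cnn;
  RnnParams rnn;
  HeadParams head;
  bool has_cnn = false, has_rnn = false;
};

static SeqModel seqmodel_load(List params, const Opts& o) {
  SeqModel M;
  if (o.use_cnn) { M.cnn = cnn_load(params["cnn"]); M.has_cnn = true; }
  if (o.use_rnn) { M.rnn = rnn_load(params["rnn"]); M.has_rnn = true; }
  M.head = head_load(params["head"]);
  return M;
}
static List seqmodel_dump(const SeqModel& M) {
  List out = List::create(_["head"] = head_dump(M.head));
  if (M.has_cnn) out["cnn"] = cnn_dump(M.cnn);
  if (M.has_rnn) out["rnn"] = rnn_dump(M.rnn);
  return out;
}

// forward pass to probabilities; eval mode, batched
static std::vector<double> seqmodel_predict_all(SeqModel& M, const arma::imat& codes,
                                                const Opts& o) {
  const int n = codes.n_rows, L = codes.n_cols;
  const int T = std::min(o.rnn_window, L), t0 = (L - T) / 2;
  std::vector<double> out(n);
  for (int s = 0; s < n; s += o.batch) {
    const int e = std::min(n, s + o.batch);
    arma::imat cb = codes.rows(s, e - 1);
    fmat feat;
    if (M.has_cnn)
      feat = cnn_forward(M.cnn, cb, false, o.leaky, o.drop_cnn, o.bn_mom, o.bn_eps,
                         nullptr, nullptr);
    if (M.has_rnn) {
      fmat fr = rnn_forward(M.rnn, cb, t0, T, false, o.drop_rnn, nullptr, nullptr);
      feat = M.has_cnn ? fmat(arma::join_rows(feat, fr)) : fr;
    }
    fmat p = sigmoid(head_forward(M.head, feat, o.leaky, nullptr));
    for (int i = s; i < e; ++i) out[i] = p(i - s, 0);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_train_seqmodel(List params, IntegerMatrix codes_, NumericVector y_,
                        IntegerMatrix vcodes_, NumericVector vy_, List opts_) {
  Opts o = parse_opts(opts_);
  SeqModel M = seqmodel_load(params, o);
  const int n = codes_.nrow(), L = codes_.ncol();
  arma::imat codes(n, L), vcodes(vcodes_.nrow(), vcodes_.ncol());
  for (int j = 0; j < L; ++j) for (int i = 0; i < n; ++i) codes(i, j) = codes_(i, j);
  for (int j = 0; j < vcodes_.ncol(); ++j)
    for (int i = 0; i < vcodes_.nrow(); ++i) vcodes(i, j) = vcodes_(i, j);
  const int T = std::min(o.rnn_window, L), t0 = (L - T) / 2;

  RNG rng(o.seed);
  RmsState S;
  std::vector<double> hist_tr, hist_vl, hist_vap;
  SeqModel best = M;
  double best_vl = INFINITY;
  int best_epoch = -1, since_best = 0;

  CnnCache cc;
  RnnCache rc;
  for (int ep = 0; ep < o.epochs; ++ep) {
    std::vector<uword> perm = rng.permutation(n);
    double ep_loss = 0;
    int nb = 0;
    for (int s = 0; s < n; s += o.batch) {
      const int e = std::min(n, s + o.batch);
      const int B = e - s;
      arma::imat cb(B, L);
      fmat yb(B, 1);
      for (int i = 0; i < B; ++i) {
        cb.row(i) = codes.row(perm[s + i]);
        yb(i, 0) = (float)y_[perm[s + i]];
      }
      fmat feat, fcnn, frnn;
      if (M.has_cnn) {
        fcnn = cnn_forward(M.cnn, cb, o.train_trunks, o.leaky, o.drop_cnn,
                           o.bn_mom, o.bn_eps, &rng, o.train_trunks ? &cc : nullptr);
        feat = fcnn;
      }
      if (M.has_rnn) {
        frnn = rnn_forward(M.rnn, cb, t0, T, o.train_trunks, o.drop_rnn, &rng,
                           o.train_trunks ? &rc : nullptr);
        feat = M.has_cnn ? fmat(arma::join_rows(fcnn, frnn)) : frnn;
      }
      HeadCache hc;
      fmat logit = head_forward(M.head, feat, o.leaky, &hc);
      fmat p = sigmoid(logit);
      // clipped binary cross-entropy
      double loss = 0;
      for (int i = 0; i < B; ++i) {
        double pi = std::min(std::max((double)p(i, 0), 1e-7), 1 - 1e-7);
        loss += -(yb(i, 0) * std::log(pi) + (1 - yb(i, 0)) * std::log(1 - pi));
      }
      loss /= B;
      if (!std::isfinite(loss))
        stop("NaN/Inf training loss at epoch %d (lr=%g, batch=%d)", ep + 1, o.lr, o.batch);
      ep_loss += loss; ++nb;

      fmat dlogit = (p - yb) / (float)B;
      HeadGrads hg;
      fmat dfeat = head_backward(M.head, hc, dlogit, o.leaky, hg);
      for (size_t j = 0; j < M.head.W.size(); ++j) {
        rms_update(S, "hW" + std::to_string(j), M.head.W[j], hg.dW[j], o.lr, o.rho, o.eps);
        rms_update(S, "hb" + std::to_string(j), M.head.b[j], hg.db[j], o.lr, o.rho, o.eps);
      }
      if (o.train_trunks) {
        int off = 0;
        if (M.has_cnn) {
          fmat dfc = dfeat.cols(0, M.cnn.Cout() - 1);
          off = M.cnn.Cout();
          CnnGrads g;
          cnn_backward(M.cnn, cc, dfc, o.leaky, g);
          rms_update(S, "cW1", M.cnn.W1, g.dW1, o.lr, o.rho, o.eps);
          rms_update(S, "cb1", M.cnn.b1, g.db1, o.lr, o.rho, o.eps);
          rms_update(S, "cg1", M.cnn.g1, g.dg1, o.lr, o.rho, o.eps);
          rms_update(S, "cbe1", M.cnn.be1, g.dbe1, o.lr, o.rho, o.eps);
          for (int j = 0; j < 3; ++j) {
            rms_update(S, "cWd" + std::to_string(j), M.cnn.Wd[j], g.dWd[j], o.lr, o.rho, o.eps);
            rms_update(S, "cbd" + std::to_string(j), M.cnn.bd[j], g.dbd[j], o.lr, o.rho, o.eps);
          }
          rms_update(S, "cg2", M.cnn.g2, g.dg2, o.lr, o.rho, o.eps);
          rms_update(S, "cbe2", M.cnn.be2, g.dbe2, o.lr, o.rho, o.eps);
        }
        if (M.has_rnn) {
          fmat dfr = dfeat.cols(off, dfeat.n_cols - 1);
          RnnGrads g;
          rnn_backward(M.rnn, rc, dfr, g);
          rms_update(S, "rW1f", M.rnn.W1f, g.dW1f, o.lr, o.rho, o.eps);
          rms_update(S, "rb1f", M.rnn.b1f, g.db1f, o.lr, o.rho, o.eps);
          rms_update(S, "rW1b", M.rnn.W1b, g.dW1b, o.lr, o.rho, o.eps);
          rms_update(S, "rb1b", M.rnn.b1b, g.db1b, o.lr, o.rho, o.eps);
          rms_update(S, "rW2f", M.rnn.W2f, g.dW2f, o.lr, o.rho, o.eps);
          rms_update(S, "rb2f", M.rnn.b2f, g.db2f, o.lr, o.rho, o.eps);
          rms_update(S, "rW2b", M.rnn.W2b, g.dW2b, o.lr, o.rho, o.eps);
          rms_update(S, "rb2b", M.rnn.b2b, g.db2b, o.lr, o.rho, o.eps);
          rms_update(S, "rWtd", M.rnn.Wtd, g.dWtd, o.lr, o.rho, o.eps);
          rms_update(S, "rbtd", M.rnn.btd, g.dbtd, o.lr, o.rho, o.eps);
        }
      }
      Rcpp::checkUserInterrupt();
    }
    ep_loss /= std::max(nb, 1);

    // validation
    std::vector<double> vp = seqmodel_predict_all(M, vcodes, o);
    double vl = 0;
    std::vector<double> vy(vy_.size());
    for (int i = 0; i < vy_.size(); ++i) {
      vy[i] = vy_[i];
      double pi = std::min(std::max(vp[i], 1e-7), 1 - 1e-7);
      vl += -(vy[i] * std::log(pi) + (1 - vy[i]) * std::log(1 - pi));
    }
    vl /= std::max((int)vy.size(), 1);
    double vap = ap_blocked(vy, vp);
    hist_tr.push_back(ep_loss); hist_vl.push_back(vl); hist_vap.push_back(vap);
    if (o.verbose)
      Rcout << "epoch " << ep + 1 << " train_loss " << ep_loss
            << " val_loss " << vl << " val_ap " << vap << "\n";
    if (vl < best_vl) { best_vl = vl; best = M; best_epoch = ep; since_best = 0; }
    else if (++since_best >= o.patience) break;
  }

  List hist = List::create(_["train_loss"] = wrap(hist_tr),
                           _["val_loss"] = wrap(hist_vl),
                           _["val_ap"] = wrap(hist_vap),
                           _["best_epoch"] = best_epoch + 1);
  return List::create(_["params"] = seqmodel_dump(best), _["history"] = hist);
}

// single-batch loss and analytic gradients (training mode, fixed RNG);
// used by the finite-difference gradient tests
// [[Rcpp::export]]
List cpp_seqmodel_loss_grads(List params, IntegerMatrix codes_, NumericVector y_,
                             List opts_) {
  Opts o = parse_opts(opts_);
  SeqModel M = seqmodel_load(params, o);
  const int B = codes_.nrow(), L = codes_.ncol();
  arma::imat cb(B, L);
  for (int j = 0; j < L; ++j) for (int i = 0; i < B; ++i) cb(i, j) = codes_(i, j);
  const int T = std::min(o.rnn_window, L), t0 = (L - T) / 2;
  RNG rng(o.seed);
  fmat yb(B, 1);
  for (int i = 0; i < B; ++i) yb(i, 0) = (float)y_[i];
  CnnCache cc; RnnCache rc;
  fmat feat, fcnn, frnn;
  if (M.has_cnn) {
    fcnn = cnn_forward(M.cnn, cb, true, o.leaky, o.drop_cnn, o.bn_mom, o.bn_eps,
                       &rng, &cc);
    feat = fcnn;
  }
  if (M.has_rnn) {
    frnn = rnn_forward(M.rnn, cb, t0, T, true, o.drop_rnn, &rng, &rc);
    feat = M.has_cnn ? fmat(arma::join_rows(fcnn, frnn)) : frnn;
  }
  HeadCache hc;
  fmat p = sigmoid(head_forward(M.head, feat, o.leaky, &hc));
  double loss = 0;
  for (int i = 0; i < B; ++i) {
    double pi = std::min(std::max((double)p(i, 0), 1e-7), 1 - 1e-7);
    loss += -(yb(i, 0) * std::log(pi) + (1 - yb(i, 0)) * std::log(1 - pi));
  }
  loss /= B;
  fmat dlogit = (p - yb) / (float)B;
  HeadGrads hg;
  fmat dfeat = head_backward(M.head, hc, dlogit, o.leaky, hg);
  List out = List::create(_["loss"] = loss);
  List hw(hg.dW.size()), hb(hg.db.size());
  for (size_t j = 0; j < hg.dW.size(); ++j) { hw[j] = wrap_fmat(hg.dW[j]); hb[j] = wrap_fvec(hg.db[j]); }
  out["head"] = List::create(_["W"] = hw, _["b"] = hb);
  int off = 0;
  if (M.has_cnn) {
    CnnGrads g;
    fmat dfc = dfeat.cols(0, M.cnn.Cout() - 1);
    off = M.cnn.Cout();
    cnn_backward(M.cnn, cc, dfc, o.leaky, g);
    out["cnn"] = List::create(
      _["W1"] = wrap_fmat(g.dW1), _["b1"] = wrap_fvec(g.db1),
      _["g1"] = wrap_fvec(g.dg1), _["be1"] = wrap_fvec(g.dbe1),
      _["Wd"] = List::create(wrap_fmat(g.dWd[0]), wrap_fmat(g.dWd[1]), wrap_fmat(g.dWd[2])),
      _["bd"] = List::create(wrap_fvec(g.dbd[0]), wrap_fvec(g.dbd[1]), wrap_fvec(g.dbd[2])),
      _["g2"] = wrap_fvec(g.dg2), _["be2"] = wrap_fvec(g.dbe2));
  }
  if (M.has_rnn) {
    RnnGrads g;
    fmat dfr = dfeat.cols(off, dfeat.n_cols - 1);
    rnn_backward(M.rnn, rc, dfr, g);
    out["rnn"] = List::create(
      _["W1f"] = wrap_fmat(g.dW1f), _["b1f"] = wrap_fvec(g.db1f),
      _["W1b"] = wrap_fmat(g.dW1b), _["b1b"] = wrap_fvec(g.db1b),
      _["W2f"] = wrap_fmat(g.dW2f), _["b2f"] = wrap_fvec(g.db2f),
      _["W2b"] = wrap_fmat(g.dW2b), _["b2b"] = wrap_fvec(g.db2b),
      _["Wtd"] = wrap_fmat(g.dWtd), _["btd"] = wrap_fvec(g.dbtd));
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_seqmodel(List params, IntegerMatrix codes_, List opts_) {
  Opts o = parse_opts(opts_);
  SeqModel M = seqmodel_load(params, o);
  arma::imat codes(codes_.nrow(), codes_.ncol());
  for (int j = 0; j < codes_.ncol(); ++j)
    for (int i = 0; i < codes_.nrow(); ++i) codes(i, j) = codes_(i, j);
  return wrap(seqmodel_predict_all(M, codes, o));
}

// trunk features (head input) in eval mode; used for model composition
// [[Rcpp::export]]
NumericMatrix cpp_trunk_features(List params, IntegerMatrix codes_, List opts_) {
  Opts o = parse_opts(opts_);
  SeqModel M = seqmodel_load(params, o);
  const int n = codes_.nrow(), L = codes_.ncol();
  arma::imat codes(n, L);
  for (int j = 0; j < L; ++j) for (int i = 0; i < n; ++i) codes(i, j) = codes_(i, j);
  const int T = std::min(o.rnn_window, L), t0 = (L - T) / 2;
  fmat out;
  for (int s = 0; s < n; s += o.batch) {
    const int e = std::min(n, s + o.batch);
    arma::imat cb = codes.rows(s, e - 1);
    fmat feat;
    if (M.has_cnn)
      feat = cnn_forward(M.cnn, cb, false, o.leaky, o.drop_cnn, o.bn_mom, o.bn_eps,
                         nullptr, nullptr);
    if (M.has_rnn) {
      fmat fr = rnn_forward(M.rnn, cb, t0, T, false, o.drop_rnn, nullptr, nullptr);
      feat = M.has_cnn ? fmat(arma::join_rows(feat, fr)) : fr;
    }
    if (out.n_elem == 0) out.set_size(n, feat.n_cols);
    out.rows(s, e - 1) = feat;
  }
  return wrap_fmat(out);
}

// ----------------------------------------------------- plain MLP (features in)

// [[Rcpp::export]]
List cpp_train_mlp(List params, NumericMatrix X_, NumericVector y_,
                   NumericMatrix Xv_, NumericVector vy_, List opts_) {
  Opts o = parse_opts(opts_);
  HeadParams H = head_load(params);
  fmat X = as_fmat(X_), Xv = as_fmat(Xv_);
  const int n = X.n_rows;
  RNG rng(o.seed);
  RmsState S;
  HeadParams best = H;
  double best_vl = INFINITY;
  int best_epoch = -1, since_best = 0;
  std::vector<double> hist_tr, hist_vl, hist_vap;
  for (int ep = 0; ep < o.epochs; ++ep) {
    std::vector<uword> perm = rng.permutation(n);
    double ep_loss = 0; int nb = 0;
    for (int s = 0; s < n; s += o.batch) {
      const int e = std::min(n, s + o.batch), B = e - s;
      fmat Xb(B, X.n_cols), yb(B, 1);
      for (int i = 0; i < B; ++i) {
        Xb.row(i) = X.row(perm[s + i]);
        yb(i, 0) = (float)y_[perm[s + i]];
      }
      fmat Din;
      if (o.drop_head > 0.0f) rng.apply_dropout(Xb, Din, o.drop_head);
      HeadCache hc;
      fmat p = sigmoid(head_forward(H, Xb, o.leaky, &hc));
      double loss = 0;
      for (int i = 0; i < B; ++i) {
        double pi = std::min(std::max((double)p(i, 0), 1e-7), 1 - 1e-7);
        loss += -(yb(i, 0) * std::log(pi) + (1 - yb(i, 0)) * std::log(1 - pi));
      }
      loss /= B;
      if (!std::isfinite(loss))
        stop("NaN/Inf training loss at epoch %d (lr=%g, batch=%d)", ep + 1, o.lr, o.batch);
      ep_loss += loss; ++nb;
      fmat dlogit = (p - yb) / (float)B;
      HeadGrads hg;
      head_backward(H, hc, dlogit, o.leaky, hg);
      for (size_t j = 0; j < H.W.size(); ++j) {
        rms_update(S, "W" + std::to_string(j), H.W[j], hg.dW[j], o.lr, o.rho, o.eps);
        rms_update(S, "b" + std::to_string(j), H.b[j], hg.db[j], o.lr, o.rho, o.eps);
      }
    }
    ep_loss /= std::max(nb, 1);
    fmat pv = sigmoid(head_forward(H, Xv, o.leaky, nullptr));
    double vl = 0;
    std::vector<double> vy(vy_.size()), vp(vy_.size());
    for (int i = 0; i < vy_.size(); ++i) {
      vy[i] = vy_[i]; vp[i] = pv(i, 0);
      double pi = std::min(std::max(vp[i], 1e-7), 1 - 1e-7);
      vl += -(vy[i] * std::log(pi) + (1 - vy[i]) * std::log(1 - pi));
    }
    vl /= std::max((int)vy.size(), 1);
    double vap = ap_blocked(vy, vp);
    hist_tr.push_back(ep_loss); hist_vl.push_back(vl); hist_vap.push_back(vap);
    if (vl < best_vl) { best_vl = vl; best = H; best_epoch = ep; since_best = 0; }
    else if (++since_best >= o.patience) break;
    Rcpp::checkUserInterrupt();
  }
  List hist = List::create(_["train_loss"] = wrap(hist_tr),
                           _["val_loss"] = wrap(hist_vl),
                           _["val_ap"] = wrap(hist_vap),
                           _["best_epoch"] = best_epoch + 1);
  return List::create(_["params"] = head_dump(best), _["history"] = hist);
}

// [[Rcpp::export]]
NumericVector cpp_predict_mlp(List params, NumericMatrix X_, double leaky) {
  HeadParams H = head_load(params);
  fmat X = as_fmat(X_);
  fmat p = sigmoid(head_forward(H, X, (float)leaky, nullptr));
  NumericVector out(p.n_rows);
  for (uword i = 0; i < p.n_rows; ++i) out[i] = p(i, 0);
  return out;
}

// forward through all head layers except the output layer: the
// penultimate dense activations, used as the per-side embedding when
// composing the loop model
// [[Rcpp::export]]
NumericMatrix cpp_head_penult(List params, NumericMatrix X_, double leaky) {
  HeadParams H = head_load(params);
  fmat A = as_fmat(X_);
  for (size_t j = 0; j + 1 < H.W.size(); ++j) {
    fmat Z = A * H.W[j];
    add_bias(Z, H.b[j]);
    lrelu_inplace(Z, (float)leaky);
    A = std::move(Z);
  }
  return wrap_fmat(A);
}

// gradient of the head logit with respect to its input features at one sample;
// exact for the piecewise-linear head, used as class weights for CAM
// [[Rcpp::export]]
NumericVector cpp_head_grad(List params, NumericVector feat, double leaky) {
  HeadParams H = head_load(params);
  fmat X(1, feat.size());
  for (int i = 0; i < feat.size(); ++i) X(0, i) = (float)feat[i];
  HeadCache hc;
  head_forward(H, X, (float)leaky, &hc);
  HeadGrads hg;
  fmat d = head_backward(H, hc, fmat(1, 1, arma::fill::ones), (float)leaky, hg);
  NumericVector out(d.n_cols);
  for (uword i = 0; i < d.n_cols; ++i) out[i] = d(0, i);
  return out;
}

// final convolutional feature maps (post BN + leaky ReLU) and pooled features
// for one sequence, eval mode; the basis of class-activation maps
// [[Rcpp::export]]
List cpp_cnn_featmaps(List params, IntegerVector codes_, List opts_) {
  Opts o = parse_opts(opts_);
  CnnParams P = cnn_load(params["cnn"]);
  arma::imat codes(1, codes_.size());
  for (int i = 0; i < codes_.size(); ++i) codes(0, i) = codes_[i];
  fmat maps;
  fmat pooled = cnn_forward(P, codes, false, o.leaky, o.drop_cnn, o.bn_mom,
                            o.bn_eps, nullptr, nullptr, &maps);
  return List::create(_["featmaps"] = wrap_fmat(maps),
                      _["pooled"] = wrap_fvec(pooled.row(0).t()));
}

// map A/C/G/T/N strings (anything else -> N) to integer codes 1..5
// [[Rcpp::export]]
IntegerMatrix cpp_encode_strings(CharacterVector seqs) {
  const int n = seqs.size();
  int L = n ? LENGTH(STRING_ELT(seqs, 0)) : 0;
  IntegerMatrix out(n, L);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    if ((int)strlen(s) != L) stop("all sequences must have equal length");
    for (int j = 0; j < L; ++j) {
      switch (s[j]) {
        case 'A': case 'a': out(i, j) = 1; break;
        case 'C': case 'c': out(i, j) = 2; break;
        case 'G': case 'g': out(i, j) = 3; break;
        case 'T': case 't': out(i, j) = 4; break;
        default: out(i, j) = 5;
      }
    }
  }
  return out;
}
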