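// Minimal deterministic neural-network engine for 1D spectral classification.
//
// Two architectures share one trainer:
//   use_conv = true : conv1d(F filters, kernel K, stride 1, valid) -> ReLU
//                     -> dropout -> maxpool(2,2) -> flatten -> dense stack
//                     -> softmax
//   use_conv = false: dense stack -> softmax (the probability refiner)
//
// Everything is float32. The dense stack runs on BLAS GEMM; the conv ->
// ReLU -> dropout -> pool -> flatten front end is a single fused pass that
// never materializes the (positions x filters) feature map - on one CPU
// the engine is memory-bandwidth-bound, so the fused kernel is what keeps
// a full cross-validation run tractable. All randomness (init, shuffling,
// dropout) flows from one integer seed through std::mt19937 / a
// counter-based 32-bit mixer, so training is bit-reproducible run to run
// on one platform.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstdint>
#include <random>
#include <vector>

using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::stop;

// counter-based 32-bit mixer (murmur3 finalizer): independent per element,
// deterministic, cheap.
static inline uint32_t mix32(uint32_t x) {
  x ^= x >> 16;
  x *= 0x85EBCA6BU;
  x ^= x >> 13;
  x *= 0xC2B2AE35U;
  x ^= x >> 16;
  return x;
}

struct Arch {
  bool use_conv;
  int P;                 // input channels
  int K, F;              // kernel size, filters
  int L, Lp;             // conv output length, pooled length
  std::vector<int> dims; // dense layer sizes: in, hidden..., out
};

struct Weights {
  fmat Wc;              // K x F
  frowvec bc;           // F
  std::vector<fmat> W;  // dense weights
  std::vector<frowvec> b;
};

// fused Adam update over one parameter array
static void adam_update(float* w, const float* g, float* m, float* v,
                        size_t n, float lr, float b1t, float b2t) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  for (size_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1.0f - b1) * g[i];
    v[i] = b2 * v[i] + (1.0f - b2) * g[i] * g[i];
    w[i] -= lr * (m[i] / b1t) / (std::sqrt(v[i] / b2t) + eps);
  }
}

struct Adam {
  std::vector<fmat> mW, vW;
  std::vector<frowvec> mb, vb;
  fmat mWc, vWc;
  frowvec mbc, vbc;
  long t = 0;
  void init(const Weights& w) {
    for (const fmat& m : w.W) {
      mW.push_back(zeros<fmat>(m.n_rows, m.n_cols));
      vW.push_back(zeros<fmat>(m.n_rows, m.n_cols));
    }
    for (const frowvec& v : w.b) {
      mb.push_back(zeros<frowvec>(v.n_elem));
      vb.push_back(zeros<frowvec>(v.n_elem));
    }
    if (w.Wc.n_elem) {
      mWc = zeros<fmat>(w.Wc.n_rows, w.Wc.n_cols);
      vWc = zeros<fmat>(w.Wc.n_rows, w.Wc.n_cols);
      mbc = zeros<frowvec>(w.bc.n_elem);
      vbc = zeros<frowvec>(w.bc.n_elem);
    }
  }
};

// He-normal initialization
static void init_weights(Weights& w, const Arch& a, std::mt19937& rng) {
  std::normal_distribution<float> nd(0.0f, 1.0f);
  if (a.use_conv) {
    w.Wc.set_size(a.K, a.F);
    float s = std::sqrt(2.0f / a.K);
    for (uword i = 0; i < w.Wc.n_elem; ++i) w.Wc(i) = s * nd(rng);
    // small positive bias keeps units alive at init: spectra inputs are
    // nonnegative, so half the filters would otherwise start dead
    w.bc = frowvec(a.F, fill::value(0.05f));
  }
  for (size_t l = 0; l + 1 < a.dims.size(); ++l) {
    fmat m(a.dims[l], a.dims[l + 1]);
    float s = std::sqrt(2.0f / a.dims[l]);
    for (uword i = 0; i < m.n_elem; ++i) m(i) = s * nd(rng);
    w.W.push_back(m);
    w.b.push_back(zeros<frowvec>(a.dims[l + 1]));
  }
}

// Per-batch conv state. The flatten feature order is j = f * Lp + l, i.e.
// H0(b, f*Lp + l) = pooled activation of filter f at pooled position l.
// gcode routes the pooled gradient with one bit per case - bit0: even
// position, positive branch; bit1: even, leaky; bit2: odd, positive;
// bit3: odd, leaky (at most one bit set). The bit layout lets the
// backward pass decode multipliers with pure integer/float arithmetic,
// which keeps the loop vectorizable. One byte per pooled element keeps
// store-bound traffic low.
struct ConvCache {
  fmat Xb;   // B x P input batch
  fmat H0;   // B x (F*Lp)
  Mat<unsigned char> gcode; // (Lp*B) x F
  float scale = 1.0f;     // dropout gradient scale used in forward
  float alpha = 0.0f;     // leaky slope used in forward
};

// Fused conv -> bias -> ReLU -> dropout -> maxpool(2,2) -> flatten.
// record: keep masks for a backward pass; dropout only applies when
// recording (training).
static void conv_forward(const Arch& a, const Weights& w, ConvCache& c,
                         bool record, float dropout, float alpha,
                         uint32_t drop_ctr) {
  const int B = c.Xb.n_rows, Lp = a.Lp, F = a.F, K = a.K;
  const bool use_drop = record && dropout > 0.0f;
  const uint32_t cut = (uint32_t)(dropout * 4294967295.0);
  const float scale = use_drop ? 1.0f / (1.0f - dropout) : 1.0f;
  c.H0.set_size(B, (uword)F * Lp);
  if (record) {
    c.gcode.set_size((uword)Lp * B, F);
    c.scale = scale;
  }
  std::vector<float> ae(B), ao(B);
  const uint32_t cut16 = cut >> 16;
  for (int l = 0; l < Lp; ++l) {
    // X columns 2l .. 2l+K for the two positions of this pool pair
    const float* xc[16]; // K <= 15 supported
    for (int k = 0; k <= K; ++k) xc[k] = c.Xb.colptr(2 * l + k);
    for (int f = 0; f < F; ++f) {
      const float* wf = w.Wc.colptr(f);
      const float bias = w.bc[f];
      if (K == 3) { // hot path: single register-resident pass
        const float w0 = wf[0], w1 = wf[1], w2 = wf[2];
        const float *x0 = xc[0], *x1 = xc[1], *x2 = xc[2], *x3 = xc[3];
        for (int b = 0; b < B; ++b) {
          ae[b] = bias + w0 * x0[b] + w1 * x1[b] + w2 * x2[b];
          ao[b] = bias + w0 * x1[b] + w1 * x2[b] + w2 * x3[b];
        }
      } else {
        for (int b = 0; b < B; ++b) { ae[b] = bias; ao[b] = bias; }
        for (int k = 0; k < K; ++k) {
          const float wk = wf[k];
          const float* x0 = xc[k];
          const float* x1 = xc[k + 1];
          for (int b = 0; b < B; ++b) {
            ae[b] += wk * x0[b];
            ao[b] += wk * x1[b];
          }
        }
      }
      float* h0 = c.H0.colptr((uword)f * Lp + l);
      if (record) {
        unsigned char* gc = c.gcode.colptr(f) + (size_t)l * B;
        c.alpha = alpha;
        const uint32_t base = drop_ctr +
            ((uint32_t)f * (uint32_t)Lp + (uint32_t)l) * 2654435761U;
        const float ascale = alpha * scale;
        for (int b = 0; b < B; ++b) {
          int pe = ae[b] > 0.0f, po = ao[b] > 0.0f;
          int de = 1, dout = 1;
          if (use_drop) {
            uint32_t h = mix32(base + (uint32_t)b);
            de = (h & 0xFFFFu) >= cut16;
            dout = (h >> 16) >= cut16;
          }
          float ke = (pe ? scale : ascale) * de;
          float ko = (po ? scale : ascale) * dout;
          float ve = ae[b] * ke, vo = ao[b] * ko;
          int win = ve >= vo;
          h0[b] = win ? ve : vo;
          // route the pooled gradient to the surviving winner, if any,
          // remembering which activation branch it sat on
          int qe = win * de * (2 - pe);
          int qo = (1 - win) * dout * (2 - po);
          gc[b] = (unsigned char)(qe | (qo << 2));
        }
      } else {
        for (int b = 0; b < B; ++b) {
          float ve = ae[b] > 0.0f ? ae[b] : alpha * ae[b];
          float vo = ao[b] > 0.0f ? ao[b] : alpha * ao[b];
          h0[b] = ve >= vo ? ve : vo;
        }
      }
    }
  }
}

// Fused conv backward: consumes the gradient at H0 (delta, B x F*Lp),
// accumulates dWc / dbc, and optionally the input gradient dX. The
// feature-map gradient is never materialized.
static void conv_backward(const Arch& a, const Weights& w, ConvCache& c,
                          const fmat& delta, fmat& dWc, frowvec& dbc,
                          fmat* dX) {
  const int B = c.Xb.n_rows, Lp = a.Lp, F = a.F, K = a.K;
  dWc.zeros(K, F);
  dbc.zeros(F);
  if (dX) dX->zeros(B, a.P);
  std::vector<float> ge(B), go(B);
  for (int l = 0; l < Lp; ++l) {
    const float* xc[16];
    for (int k = 0; k <= K; ++k) xc[k] = c.Xb.colptr(2 * l + k);
    for (int f = 0; f < F; ++f) {
      const float* dp = delta.colptr((uword)f * Lp + l);
      const unsigned char* gc = c.gcode.colptr(f) + (size_t)l * B;
      const float scale = c.scale;
      const float ascale = c.alpha * c.scale;
      float gb = 0.0f;
      float* dwf = dWc.colptr(f);
      if (K == 3) { // hot path: mask + six dot products in one pass
        const float *x0 = xc[0], *x1 = xc[1], *x2 = xc[2], *x3 = xc[3];
        float s0 = 0.0f, s1 = 0.0f, s2 = 0.0f, t0 = 0.0f, t1 = 0.0f,
              t2 = 0.0f;
        for (int b = 0; b < B; ++b) {
          const int g = gc[b];
          const float me = scale * (g & 1) + ascale * ((g >> 1) & 1);
          const float mo = scale * ((g >> 2) & 1) + ascale * ((g >> 3) & 1);
          const float e = dp[b] * me, o = dp[b] * mo;
          ge[b] = e;
          go[b] = o;
          gb += e + o;
          s0 += e * x0[b];
          s1 += e * x1[b];
          s2 += e * x2[b];
          t0 += o * x1[b];
          t1 += o * x2[b];
          t2 += o * x3[b];
        }
        dwf[0] += s0 + t0;
        dwf[1] += s1 + t1;
        dwf[2] += s2 + t2;
      } else {
        for (int b = 0; b < B; ++b) {
          const int g = gc[b];
          const float me = scale * (g & 1) + ascale * ((g >> 1) & 1);
          const float mo = scale * ((g >> 2) & 1) + ascale * ((g >> 3) & 1);
          const float e = dp[b] * me, o = dp[b] * mo;
          ge[b] = e;
          go[b] = o;
          gb += e + o;
        }
        for (int k = 0; k < K; ++k) {
          const float* x0 = xc[k];
          const float* x1 = xc[k + 1];
          float s0 = 0.0f, s1 = 0.0f;
          for (int b = 0; b < B; ++b) {
            s0 += ge[b] * x0[b];
            s1 += go[b] * x1[b];
          }
          dwf[k] += s0 + s1;
        }
      }
      dbc[f] += gb;
      if (dX) {
        const float* wf = w.Wc.colptr(f);
        for (int k = 0; k < K; ++k) {
          float* d0 = dX->colptr(2 * l + k);
          float* d1 = dX->colptr(2 * l + k + 1);
          const float wk = wf[k];
          for (int b = 0; b < B; ++b) {
            d0[b] += wk * ge[b];
            d1[b] += wk * go[b];
          }
        }
      }
    }
  }
}

// dense forward; returns softmax probabilities, stores hidden activations.
// acts holds pointers: acts[0] = input (not copied), later = owned hidden.
static fmat dense_forward(const fmat& H0, const Weights& w,
                          std::vector<fmat>& hidden, float alpha) {
  hidden.clear();
  fmat h;
  const fmat* cur = &H0;
  const size_t nl = w.W.size();
  for (size_t l = 0; l < nl; ++l) {
    h = (*cur) * w.W[l];
    h.each_row() += w.b[l];
    if (l + 1 < nl) {
      float* p = h.memptr();
      for (uword i = 0; i < h.n_elem; ++i)
        p[i] = p[i] > 0.0f ? p[i] : alpha * p[i];
      hidden.push_back(h);
      cur = &hidden.back();
    }
  }
  fcolvec mx = arma::max(h, 1);
  h.each_col() -= mx;
  h = exp(h);
  fcolvec s = sum(h, 1);
  h.each_col() /= s;
  return h;
}

struct BatchGrads {
  std::vector<fmat> dW;
  std::vector<frowvec> db;
  fmat dWc;
  frowvec dbc;
};

// backward through the dense stack; returns the gradient at the stack
// input (H0 for the conv net, X for the plain MLP)
static fmat dense_backward(const fmat& input, const Weights& w,
                           const std::vector<fmat>& hidden, fmat dZ,
                           BatchGrads& g, float alpha) {
  const size_t nl = w.W.size();
  g.dW.assign(nl, fmat());
  g.db.assign(nl, frowvec());
  fmat delta = dZ;
  for (size_t l = nl; l-- > 0;) {
    const fmat& act = (l == 0) ? input : hidden[l - 1];
    g.dW[l] = act.t() * delta;
    g.db[l] = sum(delta, 0);
    delta = delta * w.W[l].t();
    if (l > 0) {
      // post-activation sign identifies the branch (act < 0 <=> leaky)
      const float* ap = hidden[l - 1].memptr();
      float* d = delta.memptr();
      for (uword i = 0; i < delta.n_elem; ++i)
        if (ap[i] <= 0.0f) d[i] *= alpha;
    }
  }
  return delta;
}

static Arch make_arch(bool use_conv, int P, int K, int F,
                      const std::vector<int>& fc, int n_classes) {
  Arch a;
  a.use_conv = use_conv;
  a.P = P;
  a.K = K;
  a.F = F;
  if (use_conv) {
    if (K < 1 || K > 15) stop("kernel size must be in 1..15");
    if (P < K) stop("input length shorter than convolution kernel");
    a.L = P - K + 1;
    a.Lp = a.L / 2;
    if (a.Lp < 1) stop("input too short for pooling");
    a.dims.push_back(a.F * a.Lp);
  } else {
    a.L = a.Lp = 0;
    a.dims.push_back(P);
  }
  for (int h : fc) a.dims.push_back(h);
  a.dims.push_back(n_classes);
  return a;
}

static Weights weights_from_list(const List& wl, const Arch& a) {
  Weights w;
  if (a.use_conv) {
    w.Wc = conv_to<fmat>::from(Rcpp::as<mat>(wl["Wc"]));
    w.bc = conv_to<frowvec>::from(Rcpp::as<rowvec>(wl["bc"]));
  }
  List Wl = wl["W"], bl = wl["b"];
  for (int i = 0; i < Wl.size(); ++i) {
    w.W.push_back(conv_to<fmat>::from(Rcpp::as<mat>(Wl[i])));
    w.b.push_back(conv_to<frowvec>::from(Rcpp::as<rowvec>(bl[i])));
  }
  return w;
}

static List weights_to_list(const Weights& w, bool use_conv) {
  List Wl(w.W.size()), bl(w.b.size());
  for (size_t i = 0; i < w.W.size(); ++i) {
    Wl[i] = Rcpp::wrap(conv_to<mat>::from(w.W[i]));
    bl[i] = Rcpp::wrap(conv_to<rowvec>::from(w.b[i]));
  }
  List out = List::create(Named("W") = Wl, Named("b") = bl);
  if (use_conv) {
    out["Wc"] = Rcpp::wrap(conv_to<mat>::from(w.Wc));
    out["bc"] = Rcpp::wrap(conv_to<rowvec>::from(w.bc));
  }
  return out;
}

// forward pass for evaluation (no dropout); probabilities only
static fmat eval_probs(const fmat& X, const Arch& a, const Weights& w,
                       int batch, float alpha) {
  const int n = X.n_rows;
  fmat out(n, a.dims.back());
  std::vector<fmat> hidden;
  ConvCache c;
  for (int s = 0; s < n; s += batch) {
    int e = std::min(n, s + batch) - 1;
    fmat probs;
    if (a.use_conv) {
      c.Xb = X.rows(s, e);
      conv_forward(a, w, c, false, 0.0f, alpha, 0);
      probs = dense_forward(c.H0, w, hidden, alpha);
    } else {
      fmat Xb = X.rows(s, e);
      probs = dense_forward(Xb, w, hidden, alpha);
    }
    out.rows(s, e) = probs;
  }
  return out;
}

// weighted cross-entropy loss and accuracy
static void eval_metrics(const fmat& probs, const uvec& y, const fvec& cw,
                         double& loss, double& acc) {
  const int n = probs.n_rows;
  double ls = 0.0, wsum = 0.0;
  int correct = 0;
  for (int i = 0; i < n; ++i) {
    float pi = std::max(probs(i, y[i]), 1e-12f);
    ls += cw[y[i]] * -std::log((double)pi);
    wsum += cw[y[i]];
    uword am = probs.row(i).index_max();
    if ((int)am == (int)y[i]) ++correct;
  }
  loss = ls / wsum;
  acc = (double)correct / n;
}

// [[Rcpp::export]]
List nn_train_cpp(const arma::mat& Xr, const arma::ivec& yr,
                  const arma::mat& Xvr, const arma::ivec& yvr, bool use_conv,
                  int n_classes, int filters, int kernel,
                  const arma::ivec& fc_sizes, double dropout, double leaky,
                  int epochs, int batch, double lr0, double clip_norm,
                  int patience, double factor,
                  const arma::vec& class_weights, int seed,
                  bool restore_best) {
  const float alpha = (float)leaky;
  fmat X = conv_to<fmat>::from(Xr);
  uvec y = conv_to<uvec>::from(yr);
  const bool has_val = Xvr.n_rows > 0;
  fmat Xv;
  uvec yv;
  if (has_val) {
    Xv = conv_to<fmat>::from(Xvr);
    yv = conv_to<uvec>::from(yvr);
  }
  const int n = X.n_rows, P = X.n_cols;
  std::vector<int> fc(fc_sizes.begin(), fc_sizes.end());
  Arch a = make_arch(use_conv, P, kernel, filters, fc, n_classes);
  fvec cw = conv_to<fvec>::from(class_weights);

  std::mt19937 rng((uint32_t)seed);
  Weights w;
  init_weights(w, a, rng);
  Adam opt;
  opt.init(w);

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  double lr = lr0;
  double best = std::numeric_limits<double>::infinity();
  int stall = 0;
  Weights best_w;
  bool have_best = false;
  std::vector<double> tr_loss(epochs), tr_acc(epochs), va_loss(epochs),
      va_acc(epochs), lrs(epochs);
  uint32_t drop_ctr = (uint32_t)seed * 2654435761U;

  ConvCache c;
  std::vector<fmat> hidden;
  BatchGrads g;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0, ep_w = 0.0;
    long correct = 0;
    for (int s = 0; s < n; s += batch) {
      const int B = std::min(batch, n - s);
      uvec rows(B);
      for (int i = 0; i < B; ++i) rows[i] = idx[s + i];
      uvec yb = y.elem(rows);

      fmat probs;
      fmat XbMlp;
      if (use_conv) {
        c.Xb = X.rows(rows);
        conv_forward(a, w, c, true, (float)dropout, alpha, drop_ctr);
        drop_ctr += 0x9E3779B9U;
        probs = dense_forward(c.H0, w, hidden, alpha);
      } else {
        XbMlp = X.rows(rows);
        probs = dense_forward(XbMlp, w, hidden, alpha);
      }
      fmat dZ = probs;
      double wsum = 0.0;
      for (int i = 0; i < B; ++i) {
        dZ(i, yb[i]) -= 1.0f;
        float wi = cw[yb[i]];
        if (wi != 1.0f) dZ.row(i) *= wi;
        wsum += wi;
        float pi = std::max(probs(i, yb[i]), 1e-12f);
        ep_loss += wi * -std::log((double)pi);
        uword am = probs.row(i).index_max();
        if ((int)am == (int)yb[i]) ++correct;
      }
      ep_w += wsum;
      dZ /= (float)wsum;

      if (use_conv) {
        fmat dH0 = dense_backward(c.H0, w, hidden, dZ, g, alpha);
        conv_backward(a, w, c, dH0, g.dWc, g.dbc, nullptr);
      } else {
        dense_backward(XbMlp, w, hidden, dZ, g, alpha);
      }

      // global gradient-norm clipping: tames the first-epoch logit
      // oscillations that can park training in the uniform-prediction
      // basin before the data signal takes hold
      if (clip_norm > 0) {
        double sq = 0.0;
        for (const fmat& gm : g.dW) sq += accu(square(gm));
        for (const frowvec& gv : g.db) sq += accu(square(gv));
        if (use_conv) sq += accu(square(g.dWc)) + accu(square(g.dbc));
        double nrm = std::sqrt(sq);
        if (nrm > clip_norm) {
          float sc = (float)(clip_norm / nrm);
          for (fmat& gm : g.dW) gm *= sc;
          for (frowvec& gv : g.db) gv *= sc;
          if (use_conv) { g.dWc *= sc; g.dbc *= sc; }
        }
      }

      opt.t += 1;
      float b1t = 1.0f - std::pow(0.9f, (float)opt.t);
      float b2t = 1.0f - std::pow(0.999f, (float)opt.t);
      for (size_t l = 0; l < w.W.size(); ++l) {
        adam_update(w.W[l].memptr(), g.dW[l].memptr(), opt.mW[l].memptr(),
                    opt.vW[l].memptr(), w.W[l].n_elem, (float)lr, b1t, b2t);
        adam_update(w.b[l].memptr(), g.db[l].memptr(), opt.mb[l].memptr(),
                    opt.vb[l].memptr(), w.b[l].n_elem, (float)lr, b1t, b2t);
      }
      if (use_conv) {
        adam_update(w.Wc.memptr(), g.dWc.memptr(), opt.mWc.memptr(),
                    opt.vWc.memptr(), w.Wc.n_elem, (float)lr, b1t, b2t);
        adam_update(w.bc.memptr(), g.dbc.memptr(), opt.mbc.memptr(),
                    opt.vbc.memptr(), w.bc.n_elem, (float)lr, b1t, b2t);
      }
    }
    tr_loss[ep] = ep_loss / ep_w;
    tr_acc[ep] = (double)correct / n;
    if (has_val) {
      fmat pv = eval_probs(Xv, a, w, batch, alpha);
      eval_metrics(pv, yv, cw, va_loss[ep], va_acc[ep]);
    } else {
      va_loss[ep] = NA_REAL;
      va_acc[ep] = NA_REAL;
    }
    lrs[ep] = lr;
    // reduce-on-plateau on validation loss (training loss if no val set)
    double monitored = has_val ? va_loss[ep] : tr_loss[ep];
    if (monitored < best - 1e-5) {
      best = monitored;
      stall = 0;
      if (restore_best && has_val) {
        best_w = w; // snapshot at the best validation loss
        have_best = true;
      }
    } else if (++stall > patience) {
      lr *= factor;
      stall = 0;
    }
  }
  if (restore_best && have_best) w = best_w;

  List out = weights_to_list(w, use_conv);
  out["history"] = List::create(
      Named("train_loss") = tr_loss, Named("train_acc") = tr_acc,
      Named("val_loss") = va_loss, Named("val_acc") = va_acc,
      Named("lr") = lrs);
  return out;
}

// [[Rcpp::export]]
arma::mat nn_predict_cpp(const List& weights, const arma::mat& Xr,
                         bool use_conv, int n_classes, int filters,
                         int kernel, const arma::ivec& fc_sizes,
                         double leaky, int batch) {
  fmat X = conv_to<fmat>::from(Xr);
  std::vector<int> fc(fc_sizes.begin(), fc_sizes.end());
  Arch a = make_arch(use_conv, X.n_cols, kernel, filters, fc, n_classes);
  Weights w = weights_from_list(weights, a);
  fmat probs = eval_probs(X, a, w, batch, (float)leaky);
  return conv_to<mat>::from(probs);
}

// Mean absolute input gradient of the top logit, per channel.
// Dropout off; gradient taken at the predicted (max-probability) class.
// [[Rcpp::export]]
arma::vec nn_saliency_cpp(const List& weights, const arma::mat& Xr,
                          bool use_conv, int n_classes, int filters,
                          int kernel, const arma::ivec& fc_sizes,
                          double leaky, int batch) {
  const float alpha = (float)leaky;
  fmat X = conv_to<fmat>::from(Xr);
  const int n = X.n_rows, P = X.n_cols;
  std::vector<int> fc(fc_sizes.begin(), fc_sizes.end());
  Arch a = make_arch(use_conv, P, kernel, filters, fc, n_classes);
  Weights w = weights_from_list(weights, a);

  vec sal(P, fill::zeros);
  ConvCache c;
  std::vector<fmat> hidden;
  BatchGrads g;
  for (int s = 0; s < n; s += batch) {
    int e = std::min(n, s + batch) - 1;
    const int B = e - s + 1;
    fmat probs;
    fmat XbMlp;
    if (a.use_conv) {
      c.Xb = X.rows(s, e);
      // record masks, no dropout
      conv_forward(a, w, c, true, 0.0f, alpha, 0);
      probs = dense_forward(c.H0, w, hidden, alpha);
    } else {
      XbMlp = X.rows(s, e);
      probs = dense_forward(XbMlp, w, hidden, alpha);
    }
    // gradient of the winning logit: seed dZ with its one-hot
    fmat dZ(B, n_classes, fill::zeros);
    for (int i = 0; i < B; ++i) dZ(i, probs.row(i).index_max()) = 1.0f;
    fmat dX;
    if (a.use_conv) {
      fmat dH0 = dense_backward(c.H0, w, hidden, dZ, g, alpha);
      conv_backward(a, w, c, dH0, g.dWc, g.dbc, &dX);
    } else {
      dX = dense_backward(XbMlp, w, hidden, dZ, g, alpha);
    }
    sal += conv_to<vec>::from(sum(abs(dX), 0).t());
  }
  return sal / n;
}
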