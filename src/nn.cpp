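// Tooth-type-conditioned recurrent U-Net, single precision.
//
// Per-view shared-weight U-Net (3x3 same-padding convs, batch norm between
// convolution and ReLU, 2x2 max pooling, 2x2-stride-2 transposed-conv
// upsampling), auxiliary 1x1 sigmoid heads on every decoder stage (deep
// supervision), and a bi-directional convolutional LSTM (3x3 kernels) over
// the view axis consuming the final decoder feature maps; forward and
// backward h-states are concatenated and reduced by a 1x1 convolution to a
// sigmoid probability map per view. Hand-derived backprop throughout,
// optimized with AdamW (decoupled weight decay, no decay on biases/BN).
//
// Tensor layout: one view image is an arma::fmat with rows = channels and
// columns = pixels in row-major order (p = r*W + c); a sequence of n views
// concatenates the views along columns.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>
using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::uword;

// ---------------- parameters & optimizer ---------------------------------

struct Param {
  fmat W, g, m, v;
  bool decay = true;
  void init_size(int r, int c) {
    W.zeros(r, c); g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
  void he_init(std::mt19937 &rng, double fan_in) {
    std::normal_distribution<float> N(0.0f, (float)std::sqrt(2.0 / fan_in));
    for (uword i = 0; i < W.n_elem; ++i) W[i] = N(rng);
  }
  void adamw(double lr, double wd, int t, double scale) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    fmat grad = g * (float)scale;
    m = b1 * m + (1.0f - b1) * grad;
    v = b2 * v + (1.0f - b2) * (grad % grad);
    float c1 = 1.0f - std::pow(b1, (float)t);
    float c2 = 1.0f - std::pow(b2, (float)t);
    W -= (float)lr * ((m / c1) / (arma::sqrt(v / c2) + eps));
    if (decay) W -= (float)(lr * wd) * W;
    g.zeros();
  }
};

// ---------------- conv primitives -----------------------------------------

// 3x3 same-padding im2col; X: C x n*HW -> 9C x n*HW (offset-major rows)
static fmat im2col3(const fmat &X, int C, int H, int W, int n) {
  fmat col(9 * (uword)C, X.n_cols, arma::fill::none);
  int HW = H * W;
  for (int off = 0; off < 9; ++off) {
    int dr = off / 3 - 1, dc = off % 3 - 1;
    int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
    int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
    for (int v = 0; v < n; ++v) {
      for (int r = 0; r < H; ++r) {
        uword base = (uword)v * HW + (uword)r * W;
        float *dst0 = col.colptr(base) + off * C;
        const uword stride = col.n_rows;
        if (r < r0 || r >= r1 || c1 <= c0) {
          for (int c = 0; c < W; ++c) {
            float *d = dst0 + (uword)c * stride;
            for (int ch = 0; ch < C; ++ch) d[ch] = 0.0f;
          }
          continue;
        }
        const float *srcrow = X.colptr((uword)v * HW + (uword)(r + dr) * W);
        for (int c = 0; c < W; ++c) {
          float *d = dst0 + (uword)c * stride;
          if (c < c0 || c >= c1) {
            for (int ch = 0; ch < C; ++ch) d[ch] = 0.0f;
          } else {
            const float *s = srcrow + (uword)(c + dc) * C;
            for (int ch = 0; ch < C; ++ch) d[ch] = s[ch];
          }
        }
      }
    }
  }
  return col;
}

// adjoint of im2col3: scatter-add 9C x n*HW back to C x n*HW
static fmat col2im3(const fmat &col, int C, int H, int W, int n) {
  fmat X(C, col.n_cols, arma::fill::zeros);
  int HW = H * W;
  const uword stride = col.n_rows;
  for (int off = 0; off < 9; ++off) {
    int dr = off / 3 - 1, dc = off % 3 - 1;
    int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
    int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
    if (c1 <= c0) continue;
    for (int v = 0; v < n; ++v) {
      for (int r = r0; r < r1; ++r) {
        const float *s0 = col.colptr((uword)v * HW + (uword)r * W) + off * C;
        float *d0 = X.colptr((uword)v * HW + (uword)(r + dr) * W);
        for (int c = c0; c < c1; ++c) {
          const float *s = s0 + (uword)c * stride;
          float *d = d0 + (uword)(c + dc) * C;
          for (int ch = 0; ch < C; ++ch) d[ch] += s[ch];
        }
      }
    }
  }
  return X;
}

struct Conv3 {                 // 3x3 same conv, Cin -> Cout
  Param W, b;                  // W: Cout x 9Cin, b: Cout x 1
  int Cin = 0, Cout = 0;
  fmat col_cache;
  void build(std::mt19937 &rng, int cin, int cout) {
    Cin = cin; Cout = cout;
    W.init_size(cout, 9 * cin);
    W.he_init(rng, 9.0 * cin);
    b.init_size(cout, 1);
    b.decay = false;
  }
  fmat fwd(const fmat &X, int H, int Wd, int n, bool train) {
    fmat col = im2col3(X, Cin, H, Wd, n);
    fmat Y = W.W * col;
    Y.each_col() += b.W.col(0);
    if (train) col_cache = std::move(col);
    return Y;
  }
  fmat bwd(const fmat &dY, int H, int Wd, int n) {
    W.g += dY * col_cache.t();
    b.g += arma::sum(dY, 1);
    fmat dcol = W.W.t() * dY;
    col_cache.reset();
    return col2im3(dcol, Cin, H, Wd, n);
  }
};

struct Conv1 {                 // 1x1 conv
  Param W, b;
  int Cin = 0, Cout = 0;
  fmat in_cache;
  void build(std::mt19937 &rng, int cin, int cout) {
    Cin = cin; Cout = cout;
    W.init_size(cout, cin);
    W.he_init(rng, cin);
    b.init_size(cout, 1);
    b.decay = false;
  }
  fmat fwd(const fmat &X, bool train) {
    if (train) in_cache = X;
    fmat Y = W.W * X;
    Y.each_col() += b.W.col(0);
    return Y;
  }
  fmat bwd(const fmat &dY) {
    W.g += dY * in_cache.t();
    b.g += arma::sum(dY, 1);
    return W.W.t() * dY;
  }
};

struct BatchNorm {
  Param gamma, beta;
  fmat run_mean, run_var;       // buffers
  fmat xhat_cache;
  arma::fvec invstd_cache;
  int C = 0;
  void build(int c) {
    C = c;
    gamma.init_size(c, 1); gamma.W.ones(); gamma.decay = false;
    beta.init_size(c, 1); beta.decay = false;
    run_mean.zeros(c, 1); run_var.ones(c, 1);
  }
  // mode 0: running statistics; mode 1: batch statistics, update running
  // buffers (training); mode 2: batch statistics, no update (inference
  // normalizes each view sequence by its own statistics, matching the
  // statistics regime the weights were trained under)
  fmat fwd(const fmat &X, int mode) {
    const float eps = 1e-5f, mom = 0.1f;
    const uword N = X.n_cols;
    fmat Y(C, N, arma::fill::none);
    if (mode >= 1) {
      std::vector<double> s1(C, 0.0), s2(C, 0.0);
      for (uword j = 0; j < N; ++j) {
        const float *x = X.colptr(j);
        for (int ch = 0; ch < C; ++ch) {
          s1[ch] += x[ch];
          s2[ch] += (double)x[ch] * x[ch];
        }
      }
      arma::fvec mu(C), invstd(C);
      for (int ch = 0; ch < C; ++ch) {
        double m = s1[ch] / N;
        double var = std::max(0.0, s2[ch] / N - m * m);
        mu[ch] = (float)m;
        invstd[ch] = (float)(1.0 / std::sqrt(var + eps));
        if (mode == 1) {
          run_mean(ch, 0) = (1 - mom) * run_mean(ch, 0) + mom * (float)m;
          run_var(ch, 0) = (1 - mom) * run_var(ch, 0) + mom * (float)var;
        }
      }
      invstd_cache = invstd;
      xhat_cache.set_size(C, N);
      const float *g = gamma.W.memptr(), *b = beta.W.memptr();
      for (uword j = 0; j < N; ++j) {
        const float *x = X.colptr(j);
        float *xh = xhat_cache.colptr(j);
        float *y = Y.colptr(j);
        for (int ch = 0; ch < C; ++ch) {
          float v = (x[ch] - mu[ch]) * invstd[ch];
          xh[ch] = v;
          y[ch] = g[ch] * v + b[ch];
        }
      }
    } else {
      arma::fvec scale(C), shift(C);
      for (int ch = 0; ch < C; ++ch) {
        float is = 1.0f / std::sqrt(run_var(ch, 0) + eps);
        scale[ch] = gamma.W(ch, 0) * is;
        shift[ch] = beta.W(ch, 0) - run_mean(ch, 0) * scale[ch];
      }
      for (uword j = 0; j < N; ++j) {
        const float *x = X.colptr(j);
        float *y = Y.colptr(j);
        for (int ch = 0; ch < C; ++ch) y[ch] = scale[ch] * x[ch] + shift[ch];
      }
    }
    return Y;
  }
  fmat bwd(const fmat &dY) {
    const uword N = dY.n_cols;
    std::vector<double> sg(C, 0.0), sb(C, 0.0);
    for (uword j = 0; j < N; ++j) {
      const float *d = dY.colptr(j);
      const float *xh = xhat_cache.colptr(j);
      for (int ch = 0; ch < C; ++ch) {
        sb[ch] += d[ch];
        sg[ch] += (double)d[ch] * xh[ch];
      }
    }
    arma::fvec t1(C), t2(C), gs(C);
    for (int ch = 0; ch < C; ++ch) {
      gamma.g(ch, 0) += (float)sg[ch];
      beta.g(ch, 0) += (float)sb[ch];
      float g = gamma.W(ch, 0);
      t1[ch] = (float)(sb[ch] / N) * g;
      t2[ch] = (float)(sg[ch] / N) * g;
      gs[ch] = g;
    }
    fmat dX(C, N, arma::fill::none);
    for (uword j = 0; j < N; ++j) {
      const float *d = dY.colptr(j);
      const float *xh = xhat_cache.colptr(j);
      float *o = dX.colptr(j);
      for (int ch = 0; ch < C; ++ch) {
        o[ch] = (d[ch] * gs[ch] - t1[ch] - xh[ch] * t2[ch]) * invstd_cache[ch];
      }
    }
    xhat_cache.reset();
    return dX;
  }
};

static void relu_inplace(fmat &A) {
  float *p = A.memptr();
  for (uword i = 0; i < A.n_elem; ++i) if (p[i] < 0.0f) p[i] = 0.0f;
}
// zero the gradient wherever the cached activation was clipped
static void relu_bwd_inplace(fmat &d, const fmat &act) {
  float *dp = d.memptr();
  const float *a = act.memptr();
  for (uword i = 0; i < d.n_elem; ++i) if (a[i] <= 0.0f) dp[i] = 0.0f;
}

struct UpConv2 {               // 2x2 stride-2 transposed conv, Cin -> Cout
  Param W, b;                  // W: (Cout*4) x Cin
  int Cin = 0, Cout = 0;
  fmat in_cache;
  void build(std::mt19937 &rng, int cin, int cout) {
    Cin = cin; Cout = cout;
    W.init_size(cout * 4, cin);
    W.he_init(rng, 4.0 * cin);
    b.init_size(cout, 1);
    b.decay = false;
  }
  fmat fwd(const fmat &X, int H, int Wd, int n, bool train) {
    if (train) in_cache = X;
    fmat tmp = W.W * X;                      // (Cout*4) x n*HW
    int H2 = H * 2, W2 = Wd * 2, HW = H * Wd, HW2 = H2 * W2;
    fmat Y(Cout, (uword)n * HW2, arma::fill::zeros);
    for (int v = 0; v < n; ++v)
      for (int r = 0; r < H; ++r)
        for (int c = 0; c < Wd; ++c) {
          uword p = (uword)v * HW + (uword)r * Wd + c;
          for (int q = 0; q < 4; ++q) {
            uword po = (uword)v * HW2 + (uword)(2 * r + q / 2) * W2 + (2 * c + q % 2);
            for (int co = 0; co < Cout; ++co) Y(co, po) = tmp(co * 4 + q, p);
          }
        }
    Y.each_col() += b.W.col(0);
    return Y;
  }
  fmat bwd(const fmat &dY, int H, int Wd, int n) {
    int H2 = H * 2, W2 = Wd * 2, HW = H * Wd, HW2 = H2 * W2;
    fmat dtmp(Cout * 4, (uword)n * HW, arma::fill::zeros);
    for (int v = 0; v < n; ++v)
      for (int r = 0; r < H; ++r)
        for (int c = 0; c < Wd; ++c) {
          uword p = (uword)v * HW + (uword)r * Wd + c;
          for (int q = 0; q < 4; ++q) {
            uword po = (uword)v * HW2 + (uword)(2 * r + q / 2) * W2 + (2 * c + q % 2);
            for (int co = 0; co < Cout; ++co) dtmp(co * 4 + q, p) = dY(co, po);
          }
        }
    b.g += arma::sum(dY, 1);
    W.g += dtmp * in_cache.t();
    in_cache.reset();
    return W.W.t() * dtmp;
  }
};

// 2x2 max pooling over each view image
struct MaxPool2 {
  arma::umat idx_cache;         // C x n*HW/4, winning input column per channel
  fmat fwd(const fmat &X, int C, int H, int Wd, int n, bool train) {
    int H2 = H / 2, W2 = Wd / 2, HW = H * Wd, HW2 = H2 * W2;
    fmat Y(C, (uword)n * HW2);
    arma::umat idx(C, (uword)n * HW2);
    for (int v = 0; v < n; ++v)
      for (int r = 0; r < H2; ++r)
        for (int c = 0; c < W2; ++c) {
          uword po = (uword)v * HW2 + (uword)r * W2 + c;
          uword p00 = (uword)v * HW + (uword)(2 * r) * Wd + 2 * c;
          uword cand[4] = {p00, p00 + 1, p00 + Wd, p00 + Wd + 1};
          for (int ch = 0; ch < C; ++ch) {
            float best = X(ch, cand[0]);
            uword bi = cand[0];
            for (int q = 1; q < 4; ++q)
              if (X(ch, cand[q]) > best) { best = X(ch, cand[q]); bi = cand[q]; }
            Y(ch, po) = best;
            idx(ch, po) = bi;
          }
        }
    if (train) idx_cache = std::move(idx);
    return Y;
  }
  fmat bwd(const fmat &dY, int C, uword ncols_in) {
    fmat dX(C, ncols_in, arma::fill::zeros);
    for (uword j = 0; j < dY.n_cols; ++j)
      for (int ch = 0; ch < C; ++ch) dX(ch, idx_cache(ch, j)) += dY(ch, j);
    idx_cache.reset();
    return dX;
  }
};

static inline float sig1(float x) {
  if (x < -30.0f) return 0.0f;
  if (x > 30.0f) return 1.0f;
  return 1.0f / (1.0f + std::exp(-x));
}
static inline float tanh1(float x) {            // tanh via expf (libm tanhf is slow)
  if (x > 15.0f) return 1.0f;
  if (x < -15.0f) return -1.0f;
  return 1.0f - 2.0f / (std::exp(2.0f * x) + 1.0f);
}
static fmat sigmoidf(const fmat &x) {
  fmat y(x.n_rows, x.n_cols, arma::fill::none);
  const float *a = x.memptr();
  float *b = y.memptr();
  for (uword i = 0; i < x.n_elem; ++i) b[i] = sig1(a[i]);
  return y;
}
static fmat tanhf_mat(const fmat &x) {
  fmat y(x.n_rows, x.n_cols, arma::fill::none);
  const float *a = x.memptr();
  float *b = y.memptr();
  for (uword i = 0; i < x.n_elem; ++i) b[i] = tanh1(a[i]);
  return y;
}

// ---------------- network -------------------------------------------------

struct UNetStageCache {
  fmat relu1, relu2;            // post-activation outputs (relu2 = stage output)
};

struct SegNet {
  // config
  std::vector<int> widths;
  int in_ch = 5, rec_hidden = 32, resolution = 96;
  bool deep_supervision = true, itt_embedding = false;
  int adam_t = 0;
  std::mt19937 rng;

  // encoder/decoder layers
  std::vector<Conv3> enc1, enc2, dec1, dec2;
  std::vector<BatchNorm> ebn1, ebn2, dbn1, dbn2;
  std::vector<MaxPool2> pools;
  std::vector<UpConv2> ups;
  std::vector<Conv1> aux;       // one per decoder stage (index = stage depth)
  std::vector<Param> emb;       // optional i_tt embedding per decoder stage
  // recurrent unit
  Conv3 lstm_f, lstm_b;         // gate convs for both directions
  Conv1 head;                   // 2h -> 1

  int S() const { return (int)widths.size(); }

  void build(std::vector<int> w, int inch, int rec, int res, bool ds, bool embflag,
             unsigned seed) {
    widths = w; in_ch = inch; rec_hidden = rec; resolution = res;
    deep_supervision = ds; itt_embedding = embflag;
    rng.seed(seed);
    int s = S();
    enc1.resize(s); enc2.resize(s); ebn1.resize(s); ebn2.resize(s);
    pools.resize(s - 1);
    dec1.resize(s - 1); dec2.resize(s - 1); dbn1.resize(s - 1); dbn2.resize(s - 1);
    ups.resize(s - 1); aux.resize(s - 1); emb.resize(s - 1);
    for (int i = 0; i < s; ++i) {
      int cin = (i == 0) ? in_ch : widths[i - 1];
      enc1[i].build(rng, cin, widths[i]);
      ebn1[i].build(widths[i]);
      enc2[i].build(rng, widths[i], widths[i]);
      ebn2[i].build(widths[i]);
    }
    for (int d = 0; d < s - 1; ++d) {
      ups[d].build(rng, widths[d + 1], widths[d]);
      dec1[d].build(rng, 2 * widths[d], widths[d]);
      dbn1[d].build(widths[d]);
      dec2[d].build(rng, widths[d], widths[d]);
      dbn2[d].build(widths[d]);
      aux[d].build(rng, widths[d], 1);
      emb[d].init_size(widths[d], 1);
      emb[d].decay = false;
    }
    int w0 = widths[0];
    lstm_f.build(rng, w0 + rec_hidden, 4 * rec_hidden);
    lstm_b.build(rng, w0 + rec_hidden, 4 * rec_hidden);
    // forget-gate bias +1 (standard LSTM initialization)
    lstm_f.b.W.rows(rec_hidden, 2 * rec_hidden - 1).fill(1.0f);
    lstm_b.b.W.rows(rec_hidden, 2 * rec_hidden - 1).fill(1.0f);
    head.build(rng, 2 * rec_hidden, 1);
  }

  std::vector<Param *> params() {
    std::vector<Param *> out;
    for (int i = 0; i < S(); ++i) {
      out.push_back(&enc1[i].W); out.push_back(&enc1[i].b);
      out.push_back(&ebn1[i].gamma); out.push_back(&ebn1[i].beta);
      out.push_back(&enc2[i].W); out.push_back(&enc2[i].b);
      out.push_back(&ebn2[i].gamma); out.push_back(&ebn2[i].beta);
    }
    for (int d = 0; d < S() - 1; ++d) {
      out.push_back(&ups[d].W); out.push_back(&ups[d].b);
      out.push_back(&dec1[d].W); out.push_back(&dec1[d].b);
      out.push_back(&dbn1[d].gamma); out.push_back(&dbn1[d].beta);
      out.push_back(&dec2[d].W); out.push_back(&dec2[d].b);
      out.push_back(&dbn2[d].gamma); out.push_back(&dbn2[d].beta);
      out.push_back(&aux[d].W); out.push_back(&aux[d].b);
      out.push_back(&emb[d]);
    }
    out.push_back(&lstm_f.W); out.push_back(&lstm_f.b);
    out.push_back(&lstm_b.W); out.push_back(&lstm_b.b);
    out.push_back(&head.W); out.push_back(&head.b);
    return out;
  }

  // ------- U-Net over a batch of n views (train caches optional) ---------
  struct UNetCaches {
    std::vector<UNetStageCache> enc;      // per encoder stage
    std::vector<fmat> dec_out;            // per decoder stage (post relu2)
    std::vector<fmat> dec_relu1;
    std::vector<fmat> concat_in;          // not stored; splits derived
    float itt = 0.0f;
  };

  // forward through the U-Net; returns final feature maps (w0 x n*HW)
  fmat unet_fwd(const fmat &X, int n, int mode, UNetCaches *C,
                std::vector<fmat> *aux_logits, float itt) {
    const bool train = (mode == 1);
    int H = resolution, Wd = resolution;
    if (C) { C->enc.resize(S()); C->dec_out.resize(S() - 1); C->dec_relu1.resize(S() - 1); C->itt = itt; }
    std::vector<fmat> skips(S());
    fmat cur = X;
    for (int s = 0; s < S(); ++s) {
      int h = H >> s, w = Wd >> s;
      fmat a = enc1[s].fwd(cur, h, w, n, train);
      a = ebn1[s].fwd(a, mode);
      relu_inplace(a);
      fmat b = enc2[s].fwd(a, h, w, n, train);
      if (train && C) C->enc[s].relu1 = std::move(a);
      b = ebn2[s].fwd(b, mode);
      relu_inplace(b);
      if (s < S() - 1) cur = pools[s].fwd(b, widths[s], h, w, n, train);
      if (train && C) C->enc[s].relu2 = b;
      skips[s] = std::move(b);
    }
    fmat decout = std::move(skips[S() - 1]);
    for (int d = S() - 2; d >= 0; --d) {
      int h = H >> d, w = Wd >> d;                 // output res of this stage
      fmat up = ups[d].fwd(decout, h / 2, w / 2, n, train);
      if (itt_embedding) up.each_col() += itt * emb[d].W.col(0);
      fmat cat = arma::join_cols(up, skips[d]);
      up.reset(); skips[d].reset();
      fmat a = dec1[d].fwd(cat, h, w, n, train);
      cat.reset();
      a = dbn1[d].fwd(a, mode);
      relu_inplace(a);
      fmat b = dec2[d].fwd(a, h, w, n, train);
      if (train && C) C->dec_relu1[d] = std::move(a);
      b = dbn2[d].fwd(b, mode);
      relu_inplace(b);
      decout = std::move(b);
      if (train && C) C->dec_out[d] = decout;
      if (aux_logits) (*aux_logits)[d] = aux[d].fwd(decout, train);
    }
    return decout;
  }

  // backward through the U-Net given gradient wrt the final feature maps and
  // per-stage gradients wrt the auxiliary logits (may be empty)
  void unet_bwd(fmat dfeat, int n, UNetCaches &C, std::vector<fmat> &daux_logits) {
    int H = resolution, Wd = resolution;
    fmat ddeeper;                                  // grad wrt deeper decoder output
    for (int d = 0; d <= S() - 2; ++d) {
      int h = H >> d, w = Wd >> d;
      fmat dout = (d == 0) ? std::move(dfeat) : std::move(ddeeper);
      if (!daux_logits.empty() && daux_logits[d].n_elem > 0) {
        dout += aux[d].bwd(daux_logits[d]);
      }
      relu_bwd_inplace(dout, C.dec_out[d]);
      C.dec_out[d].reset();
      fmat db = dbn2[d].bwd(dout);
      dout.reset();
      fmat dr1 = dec2[d].bwd(db, h, w, n);
      db.reset();
      relu_bwd_inplace(dr1, C.dec_relu1[d]);
      C.dec_relu1[d].reset();
      fmat da = dbn1[d].bwd(dr1);
      dr1.reset();
      fmat dcat = dec1[d].bwd(da, h, w, n);
      da.reset();
      fmat dup = dcat.rows(0, widths[d] - 1);
      skip_grads_[d] = dcat.rows(widths[d], 2 * widths[d] - 1);
      dcat.reset();
      if (itt_embedding) emb[d].g += C.itt * arma::sum(dup, 1);
      ddeeper = ups[d].bwd(dup, h / 2, w / 2, n);
    }
    // encoder backward, bottom-up
    fmat dcur = std::move(ddeeper);                // grad wrt bottleneck output
    for (int s = S() - 1; s >= 0; --s) {
      int h = H >> s, w = Wd >> s;
      if (s < S() - 1) {
        // dcur currently holds grad wrt the pooled map of stage s
        fmat dpre = pools[s].bwd(dcur, widths[s], C.enc[s].relu2.n_cols);
        dcur = dpre + skip_grads_[s];
        skip_grads_[s].reset();
      }
      relu_bwd_inplace(dcur, C.enc[s].relu2);
      C.enc[s].relu2.reset();
      fmat db = ebn2[s].bwd(dcur);
      dcur.reset();
      fmat dr1 = enc2[s].bwd(db, h, w, n);
      db.reset();
      relu_bwd_inplace(dr1, C.enc[s].relu1);
      C.enc[s].relu1.reset();
      fmat da = ebn1[s].bwd(dr1);
      dr1.reset();
      dcur = enc1[s].bwd(da, h, w, n);             // grad wrt stage input
    }
  }

  // scratch used between unet fwd/bwd in training
  std::vector<fmat> skip_grads_;

  // ------- ConvLSTM -------------------------------------------------------
  struct LSTMCache {
    std::vector<fmat> i, f, gg, o, c, tc, xh_col;
  };

  // run one direction; feats: w0 x n*HW; returns h states per view
  std::vector<fmat> lstm_dir(const fmat &feats, int n, Conv3 &gate, bool train,
                             LSTMCache *cache, bool backward_dir) {
    int H = resolution, Wd = resolution, HW = H * Wd;
    int h = rec_hidden, w0 = widths[0];
    std::vector<fmat> hs(n);
    fmat hprev(h, HW, arma::fill::zeros), cprev(h, HW, arma::fill::zeros);
    if (cache) {
      cache->i.resize(n); cache->f.resize(n); cache->gg.resize(n);
      cache->o.resize(n); cache->c.resize(n); cache->tc.resize(n);
      cache->xh_col.resize(n);
    }
    for (int k = 0; k < n; ++k) {
      int t = backward_dir ? (n - 1 - k) : k;
      fmat xt = feats.cols((uword)t * HW, (uword)(t + 1) * HW - 1);
      fmat xh = arma::join_cols(xt, hprev);
      fmat col = im2col3(xh, w0 + h, H, Wd, 1);
      fmat gates = gate.W.W * col;
      gates.each_col() += gate.b.W.col(0);
      fmat ig = sigmoidf(gates.rows(0, h - 1));
      fmat fg = sigmoidf(gates.rows(h, 2 * h - 1));
      fmat gg = tanhf_mat(gates.rows(2 * h, 3 * h - 1));
      fmat og = sigmoidf(gates.rows(3 * h, 4 * h - 1));
      fmat c = fg % cprev + ig % gg;
      fmat tc = tanhf_mat(c);
      fmat hcur = og % tc;
      if (cache) {
        cache->i[t] = ig; cache->f[t] = fg; cache->gg[t] = gg; cache->o[t] = og;
        cache->c[t] = cprev;                      // cell state entering step t
        cache->tc[t] = tc;
        cache->xh_col[t] = std::move(col);
      }
      hs[t] = hcur;
      hprev = std::move(hcur);
      cprev = std::move(c);
    }
    return hs;
  }

  // backward through one direction: dhs = per-view grads wrt h outputs;
  // accumulates gate grads and the gradient wrt the input features
  void lstm_dir_bwd(const std::vector<fmat> &dhs, int n, Conv3 &gate,
                    LSTMCache &cache, bool backward_dir, fmat &dfeats) {
    int H = resolution, Wd = resolution, HW = H * Wd;
    int h = rec_hidden, w0 = widths[0];
    fmat dh_next(h, HW, arma::fill::zeros), dc_next(h, HW, arma::fill::zeros);
    for (int k = n - 1; k >= 0; --k) {
      int t = backward_dir ? (n - 1 - k) : k;
      fmat dh = dhs[t] + dh_next;
      fmat dtc = dh % cache.o[t];
      fmat dc = dc_next + dtc % (1.0f - cache.tc[t] % cache.tc[t]);
      fmat dog = dh % cache.tc[t];
      fmat dig = dc % cache.gg[t];
      fmat dfg = dc % cache.c[t];
      fmat dgg = dc % cache.i[t];
      fmat dgates(4 * h, (uword)HW);
      dgates.rows(0, h - 1) = dig % cache.i[t] % (1.0f - cache.i[t]);
      dgates.rows(h, 2 * h - 1) = dfg % cache.f[t] % (1.0f - cache.f[t]);
      dgates.rows(2 * h, 3 * h - 1) = dgg % (1.0f - cache.gg[t] % cache.gg[t]);
      dgates.rows(3 * h, 4 * h - 1) = dog % cache.o[t] % (1.0f - cache.o[t]);
      gate.W.g += dgates * cache.xh_col[t].t();
      gate.b.g += arma::sum(dgates, 1);
      fmat dcol = gate.W.W.t() * dgates;
      fmat dxh = col2im3(dcol, w0 + h, H, Wd, 1);
      dfeats.cols((uword)t * HW, (uword)(t + 1) * HW - 1) += dxh.rows(0, w0 - 1);
      dh_next = dxh.rows(w0, w0 + h - 1);
      dc_next = dc % cache.f[t];
    }
  }

  // ------- full forward (returns per-view final probs + aux probs) --------
  // x: in_ch x n*HW. In eval mode caches are skipped.
  void forward(const fmat &x, int n, float itt, bool train,
               fmat &final_probs, std::vector<fmat> *aux_probs,
               UNetCaches *uc, LSTMCache *cf, LSTMCache *cb,
               std::vector<fmat> *aux_logits_out, fmat *feats_out,
               std::vector<fmat> *hf_out, std::vector<fmat> *hb_out,
               fmat *hcat_out) {
    std::vector<fmat> aux_logits(S() - 1);
    // inference (mode 2) normalizes with the statistics of this sequence's
    // own views, the same regime the weights see during training (mode 1)
    fmat feats = unet_fwd(x, n, train ? 1 : 2, uc, &aux_logits, itt);
    if (train && uc) skip_grads_.assign(S(), fmat());
    std::vector<fmat> hf = lstm_dir(feats, n, lstm_f, train, cf, false);
    std::vector<fmat> hb = lstm_dir(feats, n, lstm_b, train, cb, true);
    int HW = resolution * resolution;
    fmat hcat(2 * rec_hidden, (uword)n * HW);
    for (int t = 0; t < n; ++t) {
      hcat.cols((uword)t * HW, (uword)(t + 1) * HW - 1) = arma::join_cols(hf[t], hb[t]);
    }
    fmat logits = head.fwd(hcat, train);
    final_probs = sigmoidf(logits);
    if (aux_probs) {
      aux_probs->resize(S() - 1);
      for (int d = 0; d < S() - 1; ++d) (*aux_probs)[d] = sigmoidf(aux_logits[d]);
    }
    if (aux_logits_out) *aux_logits_out = std::move(aux_logits);
    if (feats_out) *feats_out = feats;
    if (hf_out) *hf_out = std::move(hf);
    if (hb_out) *hb_out = std::move(hb);
    if (hcat_out) *hcat_out = std::move(hcat);
  }
};

// ---------------- dice loss helpers ---------------------------------------

// dice loss and gradient wrt probabilities for one view image
static double dice_and_grad(const fmat &p, const fmat &r, double eps,
                            fmat &dp) {
  double sp = 0.0, sr = 0.0, spr = 0.0;
  const float *pp = p.memptr(), *rp = r.memptr();
  for (uword i = 0; i < p.n_elem; ++i) {
    sp += pp[i];
    sr += rp[i];
    spr += (double)pp[i] * rp[i];
  }
  double den = sp + sr + eps;
  double num = 2.0 * spr + eps;
  double loss = 1.0 - num / den;
  dp.set_size(p.n_rows, p.n_cols);
  float *dpp = dp.memptr();
  float inv_d2 = (float)(1.0 / (den * den));
  float fden = (float)den, fnum = (float)num;
  for (uword i = 0; i < p.n_elem; ++i) {
    dpp[i] = -(2.0f * rp[i] * fden - fnum) * inv_d2;
  }
  return loss;
}

// ---------------- R interface ---------------------------------------------

static fmat r_seq_to_fmat(const NumericVector &x, int n, int C, int H, int W) {
  fmat out(C, (uword)n * H * W);
  const double *p = x.begin();
  for (int v = 0; v < n; ++v)
    for (int ch = 0; ch < C; ++ch)
      for (int r = 0; r < H; ++r)
        for (int c = 0; c < W; ++c) {
          size_t ridx = (size_t)v + (size_t)n * (ch + (size_t)C * (r + (size_t)H * c));
          out(ch, (uword)v * H * W + (uword)r * W + c) = (float)p[ridx];
        }
  return out;
}

static NumericVector fmat_to_r_seq(const fmat &m, int n, int H, int W) {
  // m: 1 x n*HW -> R array (n, H, W)
  NumericVector out(Dimension(n, H, W));
  for (int v = 0; v < n; ++v)
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c)
        out[(size_t)v + (size_t)n * (r + (size_t)H * c)] =
            m(0, (uword)v * H * W + (uword)r * W + c);
  return out;
}

// [[Rcpp::export]]
SEXP nn_create_cpp(IntegerVector widths, int in_ch, int rec_hidden,
                   int resolution, bool deep_supervision, bool itt_embedding,
                   int seed) {
  SegNet *net = new SegNet();
  std::vector<int> w(widths.begin(), widths.end());
  net->build(w, in_ch, rec_hidden, resolution, deep_supervision, itt_embedding,
             (unsigned)seed);
  XPtr<SegNet> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
List nn_forward_cpp(SEXP ptr_, NumericVector x, double itt, bool want_aux) {
  XPtr<SegNet> net(ptr_);
  IntegerVector dims = x.attr("dim");
  int n = dims[0], C = dims[1], H = dims[2], W = dims[3];
  if (C != net->in_ch || H != net->resolution || W != net->resolution)
    stop("input shape does not match network configuration");
  fmat X = r_seq_to_fmat(x, n, C, H, W);
  fmat probs;
  std::vector<fmat> aux_probs;
  net->forward(X, n, (float)itt, false, probs, want_aux ? &aux_probs : nullptr,
               nullptr, nullptr, nullptr, nullptr, nullptr, nullptr, nullptr,
               nullptr);
  List out;
  out["probs"] = fmat_to_r_seq(probs, n, H, W);
  if (want_aux && net->deep_supervision) {
    List al(aux_probs.size());
    for (size_t d = 0; d < aux_probs.size(); ++d) {
      int hd = H >> d, wd = W >> d;
      al[d] = fmat_to_r_seq(aux_probs[d], n, hd, wd);
    }
    out["aux"] = al;
  }
  return out;
}

// nearest-neighbour downsample of one view target (row-major p = r*W+c)
static fmat downsample_target(const fmat &t, int H, int W, int n, int factor) {
  if (factor == 1) return t;
  int H2 = H / factor, W2 = W / factor;
  fmat out(1, (uword)n * H2 * W2);
  for (int v = 0; v < n; ++v)
    for (int r = 0; r < H2; ++r)
      for (int c = 0; c < W2; ++c)
        out(0, (uword)v * H2 * W2 + (uword)r * W2 + c) =
            t(0, (uword)v * H * W + (uword)(r * factor) * W + (c * factor));
  return out;
}

// [[Rcpp::export]]
double nn_accumulate_cpp(SEXP ptr_, NumericVector x, NumericVector target,
                         double itt, double eps) {
  XPtr<SegNet> net(ptr_);
  IntegerVector dims = x.attr("dim");
  int n = dims[0], C = dims[1], H = dims[2], W = dims[3];
  if (C != net->in_ch || H != net->resolution || W != net->resolution)
    stop("input shape does not match network configuration");
  fmat X = r_seq_to_fmat(x, n, C, H, W);
  fmat T = r_seq_to_fmat(target, n, 1, H, W);
  int HW = H * W;

  fmat probs;
  SegNet::UNetCaches uc;
  SegNet::LSTMCache cf, cb;
  std::vector<fmat> aux_logits;
  fmat feats, hcat;
  std::vector<fmat> hf, hb;
  net->forward(X, n, (float)itt, true, probs, nullptr, &uc, &cf, &cb,
               &aux_logits, &feats, &hf, &hb, &hcat);

  int S = net->S();
  double total = 0.0;
  float inv_n = 1.0f / (float)n;

  // final head: per-view dice
  fmat dprobs(1, (uword)n * HW);
  for (int v = 0; v < n; ++v) {
    fmat pv = probs.cols((uword)v * HW, (uword)(v + 1) * HW - 1);
    fmat tv = T.cols((uword)v * HW, (uword)(v + 1) * HW - 1);
    fmat dp;
    total += dice_and_grad(pv, tv, eps, dp);
    dprobs.cols((uword)v * HW, (uword)(v + 1) * HW - 1) = dp * inv_n;
  }
  fmat dlogits = dprobs % probs % (1.0f - probs);
  fmat dhcat = net->head.bwd(dlogits);

  // auxiliary heads
  std::vector<fmat> daux(S - 1);
  if (net->deep_supervision) {
    for (int d = 0; d < S - 1; ++d) {
      int hd = H >> d, wd = W >> d, hwd = hd * wd;
      fmat ap = sigmoidf(aux_logits[d]);
      fmat td = downsample_target(T, H, W, n, 1 << d);
      fmat dap(1, (uword)n * hwd);
      for (int v = 0; v < n; ++v) {
        fmat pv = ap.cols((uword)v * hwd, (uword)(v + 1) * hwd - 1);
        fmat tv = td.cols((uword)v * hwd, (uword)(v + 1) * hwd - 1);
        fmat dp;
        total += dice_and_grad(pv, tv, eps, dp);
        dap.cols((uword)v * hwd, (uword)(v + 1) * hwd - 1) = dp * inv_n;
      }
      daux[d] = dap % ap % (1.0f - ap);
    }
  }

  // recurrent backward
  int h = net->rec_hidden;
  std::vector<fmat> dhf(n), dhb(n);
  for (int t = 0; t < n; ++t) {
    fmat dh = dhcat.cols((uword)t * HW, (uword)(t + 1) * HW - 1);
    dhf[t] = dh.rows(0, h - 1);
    dhb[t] = dh.rows(h, 2 * h - 1);
  }
  fmat dfeats(net->widths[0], (uword)n * HW, arma::fill::zeros);
  net->lstm_dir_bwd(dhf, n, net->lstm_f, cf, false, dfeats);
  net->lstm_dir_bwd(dhb, n, net->lstm_b, cb, true, dfeats);

  net->unet_bwd(dfeats, n, uc, daux);
  return total / n;
}

// [[Rcpp::export]]
void nn_adam_step_cpp(SEXP ptr_, double lr, double weight_decay, double scale) {
  XPtr<SegNet> net(ptr_);
  net->adam_t += 1;
  for (Param *p : net->params()) p->adamw(lr, weight_decay, net->adam_t, scale);
}

// [[Rcpp::export]]
void nn_zero_grad_cpp(SEXP ptr_) {
  XPtr<SegNet> net(ptr_);
  for (Param *p : net->params()) p->g.zeros();
}

// [[Rcpp::export]]
double nn_param_count_cpp(SEXP ptr_) {
  XPtr<SegNet> net(ptr_);
  double n = 0;
  for (Param *p : net->params()) n += (double)p->W.n_elem;
  return n;
}

// [[Rcpp::export]]
List nn_get_state_cpp(SEXP ptr_) {
  XPtr<SegNet> net(ptr_);
  std::vector<Param *> ps = net->params();
  List weights(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    weights[i] = NumericMatrix(ps[i]->W.n_rows, ps[i]->W.n_cols,
                               arma::conv_to<arma::mat>::from(ps[i]->W).begin());
  }
  // batch-norm running buffers
  std::vector<BatchNorm *> bns;
  for (int s = 0; s < net->S(); ++s) { bns.push_back(&net->ebn1[s]); bns.push_back(&net->ebn2[s]); }
  for (int d = 0; d < net->S() - 1; ++d) { bns.push_back(&net->dbn1[d]); bns.push_back(&net->dbn2[d]); }
  List buffers(2 * bns.size());
  for (size_t i = 0; i < bns.size(); ++i) {
    buffers[2 * i] = NumericVector(bns[i]->run_mean.begin(), bns[i]->run_mean.end());
    buffers[2 * i + 1] = NumericVector(bns[i]->run_var.begin(), bns[i]->run_var.end());
  }
  return List::create(_["weights"] = weights, _["buffers"] = buffers,
                      _["adam_t"] = net->adam_t);
}

// [[Rcpp::export]]
void nn_set_state_cpp(SEXP ptr_, List state) {
  XPtr<SegNet> net(ptr_);
  std::vector<Param *> ps = net->params();
  List weights = state["weights"];
  if ((size_t)weights.size() != ps.size()) stop("checkpoint does not match architecture");
  for (size_t i = 0; i < ps.size(); ++i) {
    NumericMatrix w = weights[i];
    if ((uword)w.nrow() != ps[i]->W.n_rows || (uword)w.ncol() != ps[i]->W.n_cols)
      stop("checkpoint parameter shape mismatch");
    for (uword k = 0; k < ps[i]->W.n_elem; ++k) ps[i]->W[k] = (float)w[k];
  }
  std::vector<BatchNorm *> bns;
  for (int s = 0; s < net->S(); ++s) { bns.push_back(&net->ebn1[s]); bns.push_back(&net->ebn2[s]); }
  for (int d = 0; d < net->S() - 1; ++d) { bns.push_back(&net->dbn1[d]); bns.push_back(&net->dbn2[d]); }
  List buffers = state["buffers"];
  for (size_t i = 0; i < bns.size(); ++i) {
    NumericVector rm = buffers[2 * i], rv = buffers[2 * i + 1];
    for (uword k = 0; k < bns[i]->run_mean.n_elem; ++k) {
      bns[i]->run_mean[k] = (float)rm[k];
      bns[i]->run_var[k] = (float)rv[k];
    }
  }
  net->adam_t = as<int>(state["adam_t"]);
}

// [[Rcpp::export]]
List nn_get_grads_cpp(SEXP ptr_) {
  XPtr<SegNet> net(ptr_);
  std::vector<Param *> ps = net->params();
  List out(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    out[i] = NumericMatrix(ps[i]->g.n_rows, ps[i]->g.n_cols,
                           arma::conv_to<arma::mat>::from(ps[i]->g).begin());
  }
  return out;
}
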