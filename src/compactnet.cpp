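// Native engine for the compact squeeze-and-excitation CNN.
//
// Feature maps are stored pixel-major as (L x C) float32 matrices
// (L = H*W, pixel index = row + H*col), so per-channel work (normalization,
// ReLU, pooling, SE) runs over contiguous columns and convolutions run as
// im2col + sgemm with contiguous copies. Training accumulates per-sample
// gradients across a mini-batch (bounded memory), then applies one
// SGD-momentum update per batch. Evaluation paths are free of RNG and
// therefore bitwise reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <cstdint>
#include <cstring>

using namespace arma;

static const float BN_EPS = 1e-5f;

struct ConvBlock {
  int cin, cout, stride;
  fmat W;              // (cout, 9*cin)
  fvec b, gamma, beta; // (cout)
  fmat vW; fvec vb, vgamma, vbeta;   // momentum buffers
  fmat gW; fvec gb, ggamma, gbeta;   // gradient accumulators
};

struct CNModel {
  std::vector<ConvBlock> blocks;
  bool use_se;
  int se_ratio;
  int gate; // 0 = softmax, 1 = sigmoid
  bool use_dropout;
  float dropout;
  int input_size, n_classes, fc0_width;
  int flat_dim, final_c, final_hw;
  fmat seW1, seW2; fvec seb1, seb2;
  fmat vseW1, vseW2; fvec vseb1, vseb2;
  fmat gseW1, gseW2; fvec gseb1, gseb2;
  fmat fc0W, fc1W; fvec fc0b, fc1b;
  fmat vfc0W, vfc1W; fvec vfc0b, vfc1b;
  fmat gfc0W, gfc1W; fvec gfc0b, gfc1b;
  fvec norm_mean, norm_sd; // length 3, applied to pixels scaled to [0,1]
};

struct CNDataset {
  int n, h, w;
  std::vector<uint8_t> px; // layout: i + h*j + h*w*ch + h*w*3*img
};

static inline int conv_out(int n, int s) { return (n + 2 - 3) / s + 1; }
static inline int pool_out(int n) { return (n - 1) / 2 + 1; }

// ---------------------------------------------------------------------------
// model construction and parameter marshalling

// [[Rcpp::export(name = ".cn_create")]]
SEXP cn_create(Rcpp::List config) {
  Rcpp::IntegerVector ch = config["block_channels"];
  Rcpp::IntegerVector st = config["block_strides"];
  CNModel* m = new CNModel();
  int cin = 3, sz = Rcpp::as<int>(config["input_size"]);
  m->input_size = sz;
  for (int i = 0; i < ch.size(); ++i) {
    ConvBlock blk;
    blk.cin = cin; blk.cout = ch[i]; blk.stride = st[i];
    blk.W.zeros(blk.cout, 9 * blk.cin);
    blk.b.zeros(blk.cout); blk.gamma.ones(blk.cout); blk.beta.zeros(blk.cout);
    blk.vW.zeros(size(blk.W)); blk.vb.zeros(blk.cout);
    blk.vgamma.zeros(blk.cout); blk.vbeta.zeros(blk.cout);
    m->blocks.push_back(blk);
    cin = ch[i];
    sz = pool_out(conv_out(sz, st[i]));
  }
  m->final_c = cin;
  m->final_hw = sz * sz;
  m->flat_dim = cin * sz * sz;
  m->use_se = Rcpp::as<bool>(config["use_se"]);
  m->se_ratio = Rcpp::as<int>(config["se_ratio"]);
  std::string g = Rcpp::as<std::string>(config["gate"]);
  m->gate = (g == "sigmoid") ? 1 : 0;
  m->use_dropout = Rcpp::as<bool>(config["use_dropout"]);
  m->dropout = Rcpp::as<double>(config["dropout_rate"]);
  m->fc0_width = Rcpp::as<int>(config["fc0_width"]);
  m->n_classes = Rcpp::as<int>(config["n_classes"]);
  if (m->use_se) {
    if (m->final_c % m->se_ratio != 0)
      Rcpp::stop("channel count %d not divisible by SE ratio %d",
                 m->final_c, m->se_ratio);
    int cr = m->final_c / m->se_ratio;
    m->seW1.zeros(cr, m->final_c); m->seb1.zeros(cr);
    m->seW2.zeros(m->final_c, cr); m->seb2.zeros(m->final_c);
    m->vseW1.zeros(size(m->seW1)); m->vseb1.zeros(cr);
    m->vseW2.zeros(size(m->seW2)); m->vseb2.zeros(m->final_c);
  }
  m->fc0W.zeros(m->fc0_width, m->flat_dim); m->fc0b.zeros(m->fc0_width);
  m->fc1W.zeros(m->n_classes, m->fc0_width); m->fc1b.zeros(m->n_classes);
  m->vfc0W.zeros(size(m->fc0W)); m->vfc0b.zeros(m->fc0_width);
  m->vfc1W.zeros(size(m->fc1W)); m->vfc1b.zeros(m->n_classes);
  m->norm_mean = fvec(3, fill::value(0.5f));
  m->norm_sd = fvec(3, fill::value(0.25f));
  Rcpp::XPtr<CNModel> ptr(m, true);
  return ptr;
}

// [[Rcpp::export(name = ".cn_set_input_norm")]]
void cn_set_input_norm(SEXP mp, Rcpp::NumericVector mean, Rcpp::NumericVector sd) {
  Rcpp::XPtr<CNModel> m(mp);
  for (int c = 0; c < 3; ++c) {
    m->norm_mean[c] = (float)mean[c];
    m->norm_sd[c] = (float)sd[c];
  }
}

// [[Rcpp::export(name = ".cn_get_input_norm")]]
Rcpp::List cn_get_input_norm(SEXP mp) {
  Rcpp::XPtr<CNModel> m(mp);
  return Rcpp::List::create(
    Rcpp::Named("mean") = Rcpp::NumericVector(m->norm_mean.begin(), m->norm_mean.end()),
    Rcpp::Named("sd") = Rcpp::NumericVector(m->norm_sd.begin(), m->norm_sd.end()));
}

static Rcpp::NumericVector conv_w_to_r(const ConvBlock& blk) {
  Rcpp::NumericVector v(9 * blk.cin * blk.cout);
  for (int co = 0; co < blk.cout; ++co)
    for (int r = 0; r < 9 * blk.cin; ++r)
      v[r + 9 * blk.cin * co] = blk.W(co, r);
  v.attr("dim") = Rcpp::IntegerVector::create(3, 3, blk.cin, blk.cout);
  return v;
}

static void conv_w_from_r(ConvBlock& blk, Rcpp::NumericVector v) {
  if ((int)v.size() != 9 * blk.cin * blk.cout) Rcpp::stop("conv weight size mismatch");
  for (int co = 0; co < blk.cout; ++co)
    for (int r = 0; r < 9 * blk.cin; ++r)
      blk.W(co, r) = (float)v[r + 9 * blk.cin * co];
}

static Rcpp::NumericVector vec_to_r(const fvec& x) {
  return Rcpp::NumericVector(x.begin(), x.end());
}
static Rcpp::NumericMatrix mat_to_r(const fmat& x) {
  Rcpp::NumericMatrix out(x.n_rows, x.n_cols);
  for (uword j = 0; j < x.n_cols; ++j)
    for (uword i = 0; i < x.n_rows; ++i) out(i, j) = x(i, j);
  return out;
}
static fvec vec_from_r(Rcpp::NumericVector v, uword n, const char* what) {
  if (v.size() != (int)n) Rcpp::stop("size mismatch for %s", what);
  fvec out(n);
  for (uword i = 0; i < n; ++i) out[i] = (float)v[i];
  return out;
}
static fmat mat_from_r(Rcpp::NumericMatrix v, uword r, uword c, const char* what) {
  if ((uword)v.nrow() != r || (uword)v.ncol() != c) Rcpp::stop("size mismatch for %s", what);
  fmat out(r, c);
  for (uword j = 0; j < c; ++j)
    for (uword i = 0; i < r; ++i) out(i, j) = (float)v(i, j);
  return out;
}

// [[Rcpp::export(name = ".cn_get_params")]]
Rcpp::List cn_get_params(SEXP mp) {
  Rcpp::XPtr<CNModel> m(mp);
  Rcpp::List out;
  for (size_t i = 0; i < m->blocks.size(); ++i) {
    const ConvBlock& blk = m->blocks[i];
    std::string p = "block" + std::to_string(i) + "_";
    out[p + "conv_w"] = conv_w_to_r(blk);
    out[p + "conv_b"] = vec_to_r(blk.b);
    out[p + "bn_gamma"] = vec_to_r(blk.gamma);
    out[p + "bn_beta"] = vec_to_r(blk.beta);
  }
  if (m->use_se) {
    out["se_w1"] = mat_to_r(m->seW1);
    out["se_b1"] = vec_to_r(m->seb1);
    out["se_w2"] = mat_to_r(m->seW2);
    out["se_b2"] = vec_to_r(m->seb2);
  }
  out["fc0_w"] = mat_to_r(m->fc0W);
  out["fc0_b"] = vec_to_r(m->fc0b);
  out["fc1_w"] = mat_to_r(m->fc1W);
  out["fc1_b"] = vec_to_r(m->fc1b);
  return out;
}

// [[Rcpp::export(name = ".cn_set_params")]]
void cn_set_params(SEXP mp, Rcpp::List params) {
  Rcpp::XPtr<CNModel> m(mp);
  for (size_t i = 0; i < m->blocks.size(); ++i) {
    ConvBlock& blk = m->blocks[i];
    std::string p = "block" + std::to_string(i) + "_";
    conv_w_from_r(blk, params[p + "conv_w"]);
    blk.b = vec_from_r(params[p + "conv_b"], blk.cout, "conv_b");
    blk.gamma = vec_from_r(params[p + "bn_gamma"], blk.cout, "bn_gamma");
    blk.beta = vec_from_r(params[p + "bn_beta"], blk.cout, "bn_beta");
    blk.vW.zeros(); blk.vb.zeros(); blk.vgamma.zeros(); blk.vbeta.zeros();
  }
  if (m->use_se) {
    int cr = m->final_c / m->se_ratio;
    m->seW1 = mat_from_r(params["se_w1"], cr, m->final_c, "se_w1");
    m->seb1 = vec_from_r(params["se_b1"], cr, "se_b1");
    m->seW2 = mat_from_r(params["se_w2"], m->final_c, cr, "se_w2");
    m->seb2 = vec_from_r(params["se_b2"], m->final_c, "se_b2");
    m->vseW1.zeros(); m->vseb1.zeros(); m->vseW2.zeros(); m->vseb2.zeros();
  }
  m->fc0W = mat_from_r(params["fc0_w"], m->fc0_width, m->flat_dim, "fc0_w");
  m->fc0b = vec_from_r(params["fc0_b"], m->fc0_width, "fc0_b");
  m->fc1W = mat_from_r(params["fc1_w"], m->n_classes, m->fc0_width, "fc1_w");
  m->fc1b = vec_from_r(params["fc1_b"], m->n_classes, "fc1_b");
  m->vfc0W.zeros(); m->vfc0b.zeros(); m->vfc1W.zeros(); m->vfc1b.zeros();
}

// ---------------------------------------------------------------------------
// dataset

// [[Rcpp::export(name = ".cn_dataset_create")]]
SEXP cn_dataset_create(Rcpp::IntegerVector pixels, int n, int h, int w) {
  if ((long long)pixels.size() != (long long)n * h * w * 3)
    Rcpp::stop("pixel buffer size does not match n*h*w*3");
  CNDataset* d = new CNDataset();
  d->n = n; d->h = h; d->w = w;
  d->px.resize((size_t)n * h * w * 3);
  for (size_t i = 0; i < d->px.size(); ++i) {
    int v = pixels[i];
    d->px[i] = (uint8_t)(v < 0 ? 0 : (v > 255 ? 255 : v));
  }
  return Rcpp::XPtr<CNDataset>(d, true);
}

// [[Rcpp::export(name = ".cn_dataset_size")]]
Rcpp::IntegerVector cn_dataset_size(SEXP dp) {
  Rcpp::XPtr<CNDataset> d(dp);
  return Rcpp::IntegerVector::create(d->n, d->h, d->w);
}

// Extract image `img` (0-based) as an (L x 3) normalized float map, applying
// a dihedral augmentation code (bit0 flip cols, bit1 flip rows, bit2
// transpose).
static fmat extract_image(const CNDataset& d, int img, int aug, const CNModel& m) {
  int h = d.h, w = d.w;
  if (aug != 0 && h != w) Rcpp::stop("augmentation requires square images");
  fmat out((uword)h * w, 3);
  const uint8_t* base = d.px.data() + (size_t)img * h * w * 3;
  for (int ch = 0; ch < 3; ++ch) {
    const uint8_t* plane = base + (size_t)ch * h * w;
    float mu = m.norm_mean[ch], sd = m.norm_sd[ch];
    float* dst = out.colptr(ch);
    if (aug == 0) {
      int L = h * w;
      for (int l = 0; l < L; ++l)
        dst[l] = (plane[l] / 255.0f - mu) / sd;
    } else {
      for (int j = 0; j < w; ++j) {
        for (int i = 0; i < h; ++i) {
          int si = i, sj = j;
          if (aug & 1) sj = w - 1 - sj;
          if (aug & 2) si = h - 1 - si;
          if (aug & 4) std::swap(si, sj);
          dst[i + h * j] = (plane[si + h * sj] / 255.0f - mu) / sd;
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// layers (pixel-major maps: (L x C), pixel index = i + H*j)

static void im2col(const fmat& X, int H, int W, int stride, fmat& cols,
                   int& Ho, int& Wo) {
  int C = X.n_cols;
  Ho = conv_out(H, stride); Wo = conv_out(W, stride);
  cols.set_size((uword)Ho * Wo, 9 * C);
  for (int c = 0; c < C; ++c) {
    const float* src = X.colptr(c);
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        float* dst = cols.colptr(ki + 3 * kj + 9 * c);
        for (int jo = 0; jo < Wo; ++jo) {
          int js = jo * stride - 1 + kj;
          float* d = dst + (size_t)Ho * jo;
          if (js < 0 || js >= W) {
            std::memset(d, 0, sizeof(float) * Ho);
            continue;
          }
          const float* s = src + (size_t)H * js;
          if (stride == 1) {
            // is = io - 1 + ki
            int io0 = std::max(0, 1 - ki);            // first valid io
            int io1 = std::min(Ho, H + 1 - ki);       // one past last valid
            for (int io = 0; io < io0; ++io) d[io] = 0.0f;
            if (io1 > io0)
              std::memcpy(d + io0, s + (io0 - 1 + ki),
                          sizeof(float) * (io1 - io0));
            for (int io = io1; io < Ho; ++io) d[io] = 0.0f;
          } else {
            for (int io = 0; io < Ho; ++io) {
              int is = io * stride - 1 + ki;
              d[io] = (is < 0 || is >= H) ? 0.0f : s[is];
            }
          }
        }
      }
    }
  }
}

static void col2im(const fmat& dcols, int H, int W, int C, int stride, fmat& dX) {
  int Ho = conv_out(H, stride), Wo = conv_out(W, stride);
  dX.zeros((uword)H * W, C);
  for (int c = 0; c < C; ++c) {
    float* dst = dX.colptr(c);
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const float* src = dcols.colptr(ki + 3 * kj + 9 * c);
        for (int jo = 0; jo < Wo; ++jo) {
          int js = jo * stride - 1 + kj;
          if (js < 0 || js >= W) continue;
          const float* s = src + (size_t)Ho * jo;
          float* d = dst + (size_t)H * js;
          for (int io = 0; io < Ho; ++io) {
            int is = io * stride - 1 + ki;
            if (is >= 0 && is < H) d[is] += s[io];
          }
        }
      }
    }
  }
}

static void maxpool(const fmat& A, int H, int W, fmat& P, umat& amax,
                    int& Hp, int& Wp) {
  int C = A.n_cols;
  Hp = pool_out(H); Wp = pool_out(W);
  P.set_size((uword)Hp * Wp, C);
  amax.set_size((uword)Hp * Wp, C);
  for (int c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    float* dst = P.colptr(c);
    uword* am = amax.colptr(c);
    for (int jp = 0; jp < Wp; ++jp) {
      int j0 = std::max(0, 2 * jp - 1), j1 = std::min(W - 1, 2 * jp + 1);
      for (int ip = 0; ip < Hp; ++ip) {
        int i0 = std::max(0, 2 * ip - 1), i1 = std::min(H - 1, 2 * ip + 1);
        float best = -std::numeric_limits<float>::infinity();
        uword barg = 0;
        for (int j = j0; j <= j1; ++j) {
          const float* col = src + (size_t)H * j;
          for (int i = i0; i <= i1; ++i) {
            if (col[i] > best) { best = col[i]; barg = i + (uword)H * j; }
          }
        }
        dst[ip + (size_t)Hp * jp] = best;
        am[ip + (size_t)Hp * jp] = barg;
      }
    }
  }
}

struct BlockCache {
  fmat in;        // input map (L_in x C_in)
  fmat cols;      // im2col patches (cached in training forward)
  int H, W;       // input spatial dims
  int Hc, Wc;     // conv output dims
  int Hp, Wp;     // pool output dims
  fmat Z;         // conv output pre-norm (Lc x C_out)
  fvec mu, var;   // per-channel spatial stats
  fmat A;         // post-norm post-relu
  umat amax;
};

static void block_forward(const ConvBlock& blk, const fmat& in, int H, int W,
                          BlockCache* cache, fmat& out, int& Hp, int& Wp) {
  fmat cols;
  int Hc, Wc;
  im2col(in, H, W, blk.stride, cols, Hc, Wc);
  fmat Z = cols * blk.W.t();           // (Lc x cout)
  if (cache) cache->cols = cols;
  uword L = Z.n_rows;
  fvec mu(blk.cout), var(blk.cout);
  fmat A(size(Z));
  for (int c = 0; c < blk.cout; ++c) {
    float* z = Z.colptr(c);
    float bc = blk.b[c];
    double s1 = 0.0, s2 = 0.0;
    for (uword l = 0; l < L; ++l) {
      z[l] += bc;
      s1 += z[l];
    }
    float m_ = (float)(s1 / L);
    for (uword l = 0; l < L; ++l) { float d = z[l] - m_; s2 += (double)d * d; }
    float v_ = (float)(s2 / L);
    mu[c] = m_; var[c] = v_;
    float inv = 1.0f / std::sqrt(v_ + BN_EPS);
    float g = blk.gamma[c] * inv, bb = blk.beta[c] - blk.gamma[c] * m_ * inv;
    float* a = A.colptr(c);
    for (uword l = 0; l < L; ++l) {
      float y = g * z[l] + bb;
      a[l] = y > 0.0f ? y : 0.0f;
    }
  }
  umat amax;
  maxpool(A, Hc, Wc, out, amax, Hp, Wp);
  if (cache) {
    cache->in = in; cache->H = H; cache->W = W;
    cache->Hc = Hc; cache->Wc = Wc; cache->Hp = Hp; cache->Wp = Wp;
    cache->Z = std::move(Z); cache->mu = mu; cache->var = var;
    cache->A = std::move(A); cache->amax = std::move(amax);
  }
}

// gradient w.r.t. block input (skipped when want_dx is false)
static fmat block_backward(ConvBlock& blk, const BlockCache& cc,
                           const fmat& dOut, bool want_dx) {
  uword L = (uword)cc.Hc * cc.Wc;
  fmat dA(L, blk.cout, fill::zeros);
  for (int c = 0; c < blk.cout; ++c) {   // unpool + relu mask
    float* da = dA.colptr(c);
    const float* dout = dOut.colptr(c);
    const uword* am = cc.amax.colptr(c);
    uword Lp = dOut.n_rows;
    for (uword op = 0; op < Lp; ++op) da[am[op]] += dout[op];
    const float* a = cc.A.colptr(c);
    for (uword l = 0; l < L; ++l)
      if (a[l] <= 0.0f) da[l] = 0.0f;
  }
  // normalization backward (per-channel spatial stats)
  fmat dZ(L, blk.cout);
  for (int c = 0; c < blk.cout; ++c) {
    float inv = 1.0f / std::sqrt(cc.var[c] + BN_EPS);
    const float* z = cc.Z.colptr(c);
    const float* da = dA.colptr(c);
    float* dz = dZ.colptr(c);
    double sum_dy = 0.0, sum_dy_xhat = 0.0;
    float muc = cc.mu[c];
    for (uword l = 0; l < L; ++l) {
      sum_dy += da[l];
      sum_dy_xhat += (double)da[l] * ((z[l] - muc) * inv);
    }
    blk.ggamma[c] += (float)sum_dy_xhat;
    blk.gbeta[c] += (float)sum_dy;
    float gi = blk.gamma[c] * inv;
    float c1 = (float)(sum_dy / L), c2 = (float)(sum_dy_xhat / L);
    for (uword l = 0; l < L; ++l) {
      float xhat = (z[l] - muc) * inv;
      dz[l] = gi * (da[l] - c1 - xhat * c2);
    }
  }
  blk.gW += dZ.t() * cc.cols;
  blk.gb += sum(dZ, 0).t();
  if (!want_dx) return fmat();
  fmat dcols = dZ * blk.W;
  fmat dX;
  col2im(dcols, cc.H, cc.W, blk.cin, blk.stride, dX);
  return dX;
}

struct SECache { fvec s, z1, u, g; };

static void se_forward_internal(const CNModel& m, fmat& P, SECache* cache) {
  fvec s = mean(P, 0).t();
  fvec z1 = m.seW1 * s + m.seb1;
  z1.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  fvec u = m.seW2 * z1 + m.seb2;
  fvec g;
  if (m.gate == 0) {
    fvec e = exp(u - u.max());
    g = e / accu(e);
  } else {
    g = 1.0f / (1.0f + exp(-u));
  }
  P.each_row() %= g.t();
  if (cache) { cache->s = s; cache->z1 = z1; cache->u = u; cache->g = g; }
}

struct FwdCache {
  std::vector<BlockCache> blocks;
  SECache se;
  fmat preSE;      // final pooled map before SE scaling (L x C)
  fvec flat, h0relu, h0drop, logits, logitsdrop, probs;
  fvec mask0, mask1;
};

static fvec softmax_vec(const fvec& x) {
  fvec e = exp(x - x.max());
  return e / accu(e);
}

// Full forward for one image. train=true caches everything and applies
// dropout with the supplied RNG.
static fvec forward_one(CNModel& m, const fmat& img0, bool train,
                        FwdCache* cc, std::mt19937* rng) {
  fmat cur = img0;
  int H = m.input_size, W = m.input_size;
  if (cc) cc->blocks.resize(m.blocks.size());
  for (size_t i = 0; i < m.blocks.size(); ++i) {
    fmat out;
    int Hp, Wp;
    block_forward(m.blocks[i], cur, H, W, cc ? &cc->blocks[i] : nullptr,
                  out, Hp, Wp);
    cur = std::move(out); H = Hp; W = Wp;
  }
  if (cc) cc->preSE = cur;
  if (m.use_se) se_forward_internal(m, cur, cc ? &cc->se : nullptr);
  fvec flat = vectorise(cur);   // index = pixel + L*channel
  fvec h0 = m.fc0W * flat + m.fc0b;
  h0.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  fvec h0d = h0;
  fvec mask0, mask1;
  bool drop = train && m.use_dropout && m.dropout > 0.0f;
  if (drop) {
    std::uniform_real_distribution<float> U(0.0f, 1.0f);
    float keep = 1.0f - m.dropout;
    mask0.set_size(h0.n_elem);
    for (uword i = 0; i < h0.n_elem; ++i)
      mask0[i] = (U(*rng) < keep) ? 1.0f / keep : 0.0f;
    h0d = h0 % mask0;
  }
  fvec logits = m.fc1W * h0d + m.fc1b;
  fvec logitsd = logits;
  if (drop) {
    std::uniform_real_distribution<float> U(0.0f, 1.0f);
    float keep = 1.0f - m.dropout;
    mask1.set_size(logits.n_elem);
    for (uword i = 0; i < logits.n_elem; ++i)
      mask1[i] = (U(*rng) < keep) ? 1.0f / keep : 0.0f;
    logitsd = logits % mask1;
  }
  fvec probs = softmax_vec(logitsd);
  if (cc) {
    cc->flat = std::move(flat); cc->h0relu = std::move(h0);
    cc->h0drop = std::move(h0d); cc->logits = std::move(logits);
    cc->logitsdrop = std::move(logitsd); cc->probs = probs;
    cc->mask0 = std::move(mask0); cc->mask1 = std::move(mask1);
  }
  return probs;
}

static void backward_one(CNModel& m, FwdCache& cc, int label) {
  fvec dlogitsd = cc.probs;
  dlogitsd[label] -= 1.0f;
  fvec dlogits = dlogitsd;
  if (cc.mask1.n_elem > 0) dlogits %= cc.mask1;
  m.gfc1W += dlogits * cc.h0drop.t();
  m.gfc1b += dlogits;
  fvec dh0d = m.fc1W.t() * dlogits;
  if (cc.mask0.n_elem > 0) dh0d %= cc.mask0;
  fvec dh0 = dh0d;
  for (uword i = 0; i < dh0.n_elem; ++i)
    if (cc.h0relu[i] <= 0.0f) dh0[i] = 0.0f;
  m.gfc0W += dh0 * cc.flat.t();
  m.gfc0b += dh0;
  fvec dflat = m.fc0W.t() * dh0;
  fmat dP(m.final_hw, m.final_c);
  std::memcpy(dP.memptr(), dflat.memptr(), sizeof(float) * dflat.n_elem);
  if (m.use_se) {
    const SECache& se = cc.se;
    const fmat& P = cc.preSE;   // pre-scaling map
    uword L = P.n_rows;
    fvec dg = sum(dP % P, 0).t();
    fmat dPin = dP;
    dPin.each_row() %= se.g.t();
    fvec du;
    if (m.gate == 0) {
      float dot_ = dot(dg, se.g);
      du = se.g % (dg - dot_);
    } else {
      du = dg % se.g % (1.0f - se.g);
    }
    m.gseW2 += du * se.z1.t();
    m.gseb2 += du;
    fvec dz1 = m.seW2.t() * du;
    for (uword i = 0; i < dz1.n_elem; ++i)
      if (se.z1[i] <= 0.0f) dz1[i] = 0.0f;
    m.gseW1 += dz1 * se.s.t();
    m.gseb1 += dz1;
    fvec ds = m.seW1.t() * dz1;
    dPin.each_row() += (ds / (float)L).t();
    dP = std::move(dPin);
  }
  fmat dcur = dP;
  for (int i = (int)m.blocks.size() - 1; i >= 0; --i)
    dcur = block_backward(m.blocks[i], cc.blocks[i], dcur, i > 0);
}

static void zero_grads(CNModel& m) {
  for (auto& blk : m.blocks) {
    blk.gW.zeros(size(blk.W)); blk.gb.zeros(blk.cout);
    blk.ggamma.zeros(blk.cout); blk.gbeta.zeros(blk.cout);
  }
  if (m.use_se) {
    m.gseW1.zeros(size(m.seW1)); m.gseb1.zeros(size(m.seb1));
    m.gseW2.zeros(size(m.seW2)); m.gseb2.zeros(size(m.seb2));
  }
  m.gfc0W.zeros(size(m.fc0W)); m.gfc0b.zeros(size(m.fc0b));
  m.gfc1W.zeros(size(m.fc1W)); m.gfc1b.zeros(size(m.fc1b));
}

template <typename T>
static void sgd_update(T& w, T& v, const T& g, float lr, float mom, float scale) {
  v = mom * v + g * scale;
  w -= lr * v;
}

static void apply_update(CNModel& m, float lr, float mom, int nbatch) {
  float s = 1.0f / nbatch;
  for (auto& blk : m.blocks) {
    sgd_update(blk.W, blk.vW, blk.gW, lr, mom, s);
    sgd_update(blk.b, blk.vb, blk.gb, lr, mom, s);
    sgd_update(blk.gamma, blk.vgamma, blk.ggamma, lr, mom, s);
    sgd_update(blk.beta, blk.vbeta, blk.gbeta, lr, mom, s);
  }
  if (m.use_se) {
    sgd_update(m.seW1, m.vseW1, m.gseW1, lr, mom, s);
    sgd_update(m.seb1, m.vseb1, m.gseb1, lr, mom, s);
    sgd_update(m.seW2, m.vseW2, m.gseW2, lr, mom, s);
    sgd_update(m.seb2, m.vseb2, m.gseb2, lr, mom, s);
  }
  sgd_update(m.fc0W, m.vfc0W, m.gfc0W, lr, mom, s);
  sgd_update(m.fc0b, m.vfc0b, m.gfc0b, lr, mom, s);
  sgd_update(m.fc1W, m.vfc1W, m.gfc1W, lr, mom, s);
  sgd_update(m.fc1b, m.vfc1b, m.gfc1b, lr, mom, s);
}

// ---------------------------------------------------------------------------
// exported compute entry points

// [[Rcpp::export(name = ".cn_predict")]]
Rcpp::NumericMatrix cn_predict(SEXP mp, SEXP dp, Rcpp::IntegerVector idx) {
  Rcpp::XPtr<CNModel> m(mp);
  Rcpp::XPtr<CNDataset> d(dp);
  if (d->h != m->input_size || d->w != m->input_size)
    Rcpp::stop("dataset images are %dx%d but the model expects %dx%d",
               d->h, d->w, m->input_size, m->input_size);
  Rcpp::NumericMatrix out(idx.size(), m->n_classes);
  for (int k = 0; k < idx.size(); ++k) {
    fmat img = extract_image(*d, idx[k] - 1, 0, *m);
    fvec p = forward_one(*m, img, false, nullptr, nullptr);
    for (int c = 0; c < m->n_classes; ++c) out(k, c) = p[c];
    if (k % 16 == 15) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export(name = ".cn_train_epoch")]]
double cn_train_epoch(SEXP mp, SEXP dp, Rcpp::IntegerVector order,
                      Rcpp::IntegerVector labels, Rcpp::IntegerVector aug,
                      double lr, double momentum, int batch_size, int seed) {
  Rcpp::XPtr<CNModel> m(mp);
  Rcpp::XPtr<CNDataset> d(dp);
  if (order.size() != labels.size() || order.size() != aug.size())
    Rcpp::stop("order, labels and aug must have equal length");
  if (d->h != m->input_size || d->w != m->input_size)
    Rcpp::stop("dataset images are %dx%d but the model expects %dx%d",
               d->h, d->w, m->input_size, m->input_size);
  std::mt19937 rng((uint32_t)seed);
  double total_loss = 0.0;
  int n = order.size();
  int done = 0;
  while (done < n) {
    int nb = std::min(batch_size, n - done);
    zero_grads(*m);
    for (int k = 0; k < nb; ++k) {
      int pos = done + k;
      fmat img = extract_image(*d, order[pos] - 1, aug[pos], *m);
      FwdCache cc;
      fvec p = forward_one(*m, img, true, &cc, &rng);
      int y = labels[pos];
      float loss = -std::log(std::max(p[y], 1e-12f));
      if (!std::isfinite(loss))
        Rcpp::stop("non-finite training loss encountered");
      total_loss += loss;
      backward_one(*m, cc, y);
    }
    apply_update(*m, (float)lr, (float)momentum, nb);
    done += nb;
    Rcpp::checkUserInterrupt();
  }
  return total_loss / n;
}

// Variance-calibrated initialization of the fully-connected layers:
// forwards a probe batch (evaluation mode) through the conv/SE stack, then
// rescales fc0 and fc1 weights so their pre-activation standard deviations
// are ~1 on that batch. The conv stack is already unit-variance by
// construction (per-channel normalization); this removes the attention
// module's scale shrinkage from the FC path at initialization.
// [[Rcpp::export(name = ".cn_calibrate_fc")]]
Rcpp::NumericVector cn_calibrate_fc(SEXP mp, SEXP dp,
                                    Rcpp::IntegerVector idx) {
  Rcpp::XPtr<CNModel> m(mp);
  Rcpp::XPtr<CNDataset> d(dp);
  int n = idx.size();
  fmat flats(m->flat_dim, n);
  for (int k = 0; k < n; ++k) {
    fmat cur = extract_image(*d, idx[k] - 1, 0, *m);
    int H = m->input_size, W = m->input_size;
    for (size_t i = 0; i < m->blocks.size(); ++i) {
      fmat out; int Hp, Wp;
      block_forward(m->blocks[i], cur, H, W, nullptr, out, Hp, Wp);
      cur = std::move(out); H = Hp; W = Wp;
    }
    if (m->use_se) se_forward_internal(*m, cur, nullptr);
    flats.col(k) = vectorise(cur);
  }
  fmat h0 = m->fc0W * flats;
  h0.each_col() += m->fc0b;
  float s0 = stddev(vectorise(h0));
  if (s0 > 1e-12f) { m->fc0W /= s0; m->fc0b /= s0; }
  h0 = m->fc0W * flats;
  h0.each_col() += m->fc0b;
  h0.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  fmat lg = m->fc1W * h0;
  lg.each_col() += m->fc1b;
  float s1 = stddev(vectorise(lg));
  if (s1 > 1e-12f) { m->fc1W /= s1; m->fc1b /= s1; }
  return Rcpp::NumericVector::create(s0, s1);
}

// One plain SGD-momentum step on externally supplied scalar parameters;
// exposed so the update rule itself is unit-testable against hand arithmetic.
// [[Rcpp::export(name = ".cn_sgd_step")]]
Rcpp::NumericVector cn_sgd_step(double w, double v, double grad,
                                double lr, double momentum) {
  float vv = (float)momentum * (float)v + (float)grad;
  float ww = (float)w - (float)lr * vv;
  return Rcpp::NumericVector::create(ww, vv);
}
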