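// ResNet-18 training engine for masked multi-slice MR stacks.
//
// Activations are held as float matrices of shape (C x H*W*B): image b occupies
// the column block [b*H*W, (b+1)*H*W) and within a block the column index is
// y*W + x. Column-major storage therefore keeps the channel vector of one pixel
// contiguous, which im2col exploits (channel-fastest kernel layout).
//
// Convolutions run as im2col + sgemm; im2col buffers are recomputed in the
// backward pass instead of cached so peak memory stays small.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <string>

using namespace arma;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;
static const double ADAM_B1 = 0.9, ADAM_B2 = 0.999, ADAM_EPS = 1e-8;

struct Param {
  fmat w, g, m, v;
  std::string name;
  void init(int r, int c, const std::string& nm) {
    w.zeros(r, c); g.zeros(r, c); m.zeros(r, c); v.zeros(r, c); name = nm;
  }
};

struct DataSet {
  fmat x;      // C x (H*W*n)
  int n, C, H, W;
};

// ---------------------------------------------------------------- Conv ----
struct Conv {
  int cin, cout, k, stride, pad;
  Param W;
  fmat Xin;              // cached input (when caching enabled)
  int H = 0, Wd = 0, B = 0, OH = 0, OW = 0;

  void init(int cin_, int cout_, int k_, int s_, int p_, const std::string& nm,
            std::mt19937& rng) {
    cin = cin_; cout = cout_; k = k_; stride = s_; pad = p_;
    W.init(cout, cin * k * k, nm);
    float sd = std::sqrt(2.0f / float(cin * k * k));
    std::normal_distribution<float> nd(0.0f, sd);
    for (uword i = 0; i < W.w.n_elem; ++i) W.w[i] = nd(rng);
  }

  void shapes(int Hin, int Win, int Bin) {
    H = Hin; Wd = Win; B = Bin;
    OH = (H + 2 * pad - k) / stride + 1;
    OW = (Wd + 2 * pad - k) / stride + 1;
  }

  int chunk_images() const {
    // keep the col buffer under ~4M floats
    double per_img = double(cin) * k * k * OH * OW;
    int nb = int(4.0e6 / std::max(1.0, per_img));
    if (nb < 1) nb = 1;
    if (nb > B) nb = B;
    return nb;
  }

  void im2col(const fmat& X, int b0, int nb, fmat& col) const {
    const int HW = H * Wd, OHW = OH * OW, K = cin * k * k;
    col.set_size(K, OHW * nb);
    for (int b = 0; b < nb; ++b) {
      for (int oy = 0; oy < OH; ++oy) {
        for (int ox = 0; ox < OW; ++ox) {
          float* dst = col.colptr(b * OHW + oy * OW + ox);
          for (int ky = 0; ky < k; ++ky) {
            int iy = oy * stride - pad + ky;
            for (int kx = 0; kx < k; ++kx) {
              int ix = ox * stride - pad + kx;
              float* d = dst + (ky * k + kx) * cin;
              if (iy >= 0 && iy < H && ix >= 0 && ix < Wd) {
                const float* src = X.colptr((b0 + b) * HW + iy * Wd + ix);
                std::memcpy(d, src, sizeof(float) * cin);
              } else {
                std::memset(d, 0, sizeof(float) * cin);
              }
            }
          }
        }
      }
    }
  }

  void col2im_add(const fmat& dcol, int b0, int nb, fmat& dX) const {
    const int HW = H * Wd, OHW = OH * OW;
    for (int b = 0; b < nb; ++b) {
      for (int oy = 0; oy < OH; ++oy) {
        for (int ox = 0; ox < OW; ++ox) {
          const float* src = dcol.colptr(b * OHW + oy * OW + ox);
          for (int ky = 0; ky < k; ++ky) {
            int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= H) continue;
            for (int kx = 0; kx < k; ++kx) {
              int ix = ox * stride - pad + kx;
              if (ix < 0 || ix >= Wd) continue;
              float* d = dX.colptr((b0 + b) * HW + iy * Wd + ix);
              const float* s = src + (ky * k + kx) * cin;
              for (int c = 0; c < cin; ++c) d[c] += s[c];
            }
          }
        }
      }
    }
  }

  fmat forward(const fmat& X, int Hin, int Win, int Bin, bool cache) {
    shapes(Hin, Win, Bin);
    if (cache) Xin = X;
    const int OHW = OH * OW;
    fmat Y(cout, OHW * B);
    fmat col;
    int nb = chunk_images();
    for (int b0 = 0; b0 < B; b0 += nb) {
      int nbb = std::min(nb, B - b0);
      im2col(X, b0, nbb, col);
      Y.cols(b0 * OHW, (b0 + nbb) * OHW - 1) = W.w * col.head_cols(OHW * nbb);
    }
    return Y;
  }

  fmat backward(const fmat& dY, bool want_dx = true) {
    const int OHW = OH * OW;
    fmat dX;
    if (want_dx) dX.zeros(cin, H * Wd * B);
    fmat col, dcol;
    int nb = chunk_images();
    for (int b0 = 0; b0 < B; b0 += nb) {
      int nbb = std::min(nb, B - b0);
      im2col(Xin, b0, nbb, col);
      const fmat dYc = dY.cols(b0 * OHW, (b0 + nbb) * OHW - 1);
      W.g += dYc * col.head_cols(OHW * nbb).t();
      if (want_dx) {
        dcol = W.w.t() * dYc;
        col2im_add(dcol, b0, nbb, dX);
      }
    }
    return dX;
  }
};

// ---------------------------------------------------------------- BN ------
struct BatchNorm {
  int C;
  Param gamma, beta;
  fvec rmean, rvar;        // running statistics (eval mode)
  fmat xhat;               // cache
  fvec invstd;
  bool used_train = false;

  void init(int C_, const std::string& nm) {
    C = C_;
    gamma.init(C, 1, nm + ".gamma");
    beta.init(C, 1, nm + ".beta");
    gamma.w.ones();
    rmean.zeros(C);
    rvar.ones(C);
  }

  fmat forward(const fmat& X, bool train, bool cache) {
    used_train = train;
    fvec mu, var;
    if (train) {
      mu = mean(X, 1);
      fmat Xc = X.each_col() - mu;
      var = mean(square(Xc), 1);
      invstd = 1.0f / sqrt(var + BN_EPS);
      fmat xh = Xc.each_col() % invstd;
      double n = X.n_cols;
      rmean = (1.0f - BN_MOMENTUM) * rmean + BN_MOMENTUM * mu;
      // unbiased variance for the running estimate, as in torch
      fvec uvar = var * float(n / std::max(1.0, n - 1.0));
      rvar = (1.0f - BN_MOMENTUM) * rvar + BN_MOMENTUM * uvar;
      fmat Y = (xh.each_col() % gamma.w.col(0)).each_col() + beta.w.col(0);
      if (cache) xhat = std::move(xh);
      return Y;
    } else {
      invstd = 1.0f / sqrt(rvar + BN_EPS);
      fmat xh = (X.each_col() - rmean).each_col() % invstd;
      fmat Y = (xh.each_col() % gamma.w.col(0)).each_col() + beta.w.col(0);
      if (cache) xhat = std::move(xh);
      return Y;
    }
  }

  fmat backward(const fmat& dY) {
    gamma.g += sum(dY % xhat, 1);
    beta.g += sum(dY, 1);
    if (!used_train) {
      // eval-mode normalization is per-channel affine (Grad-CAM path)
      return (dY.each_col() % (gamma.w.col(0) % invstd));
    }
    const float N = float(dY.n_cols);
    fmat dxh = dY.each_col() % gamma.w.col(0);
    fvec s1 = sum(dxh, 1);
    fvec s2 = sum(dxh % xhat, 1);
    fmat dX = dxh * N;
    dX.each_col() -= s1;
    dX -= xhat.each_col() % s2;
    dX.each_col() %= (invstd / N);
    return dX;
  }
};

// ---------------------------------------------------------------- Pool ----
struct MaxPool {                       // 3x3, stride 2, pad 1
  int C = 0, H = 0, W = 0, B = 0, OH = 0, OW = 0;
  umat idx;                            // input column of the max, per channel

  fmat forward(const fmat& X, int Hin, int Win, int Bin, bool cache) {
    C = X.n_rows; H = Hin; W = Win; B = Bin;
    OH = (H + 2 - 3) / 2 + 1; OW = (W + 2 - 3) / 2 + 1;
    const int HW = H * W, OHW = OH * OW;
    fmat Y(C, OHW * B);
    Y.fill(-std::numeric_limits<float>::infinity());
    if (cache) idx.set_size(C, OHW * B);
    for (int b = 0; b < B; ++b) {
      for (int oy = 0; oy < OH; ++oy) {
        for (int ox = 0; ox < OW; ++ox) {
          uword oc = b * OHW + oy * OW + ox;
          float* yp = Y.colptr(oc);
          for (int ky = 0; ky < 3; ++ky) {
            int iy = oy * 2 - 1 + ky;
            if (iy < 0 || iy >= H) continue;
            for (int kx = 0; kx < 3; ++kx) {
              int ix = ox * 2 - 1 + kx;
              if (ix < 0 || ix >= W) continue;
              uword ic = b * HW + iy * W + ix;
              const float* xp = X.colptr(ic);
              for (int c = 0; c < C; ++c) {
                if (xp[c] > yp[c]) {
                  yp[c] = xp[c];
                  if (cache) idx(c, oc) = ic;
                }
              }
            }
          }
        }
      }
    }
    return Y;
  }

  fmat backward(const fmat& dY) {
    fmat dX(C, H * W * B, fill::zeros);
    for (uword j = 0; j < dY.n_cols; ++j)
      for (int c = 0; c < C; ++c)
        dX(c, idx(c, j)) += dY(c, j);
    return dX;
  }
};

// ---------------------------------------------------------------- Block ---
struct Block {
  Conv c1, c2;
  BatchNorm b1, b2;
  bool down = false;
  Conv cd; BatchNorm bd;
  fmat r1, out;            // caches: post-relu1 and block output

  void init(int cin, int cout, int stride, const std::string& nm, std::mt19937& rng) {
    c1.init(cin, cout, 3, stride, 1, nm + ".conv1", rng);
    b1.init(cout, nm + ".bn1");
    c2.init(cout, cout, 3, 1, 1, nm + ".conv2", rng);
    b2.init(cout, nm + ".bn2");
    down = (stride != 1 || cin != cout);
    if (down) {
      cd.init(cin, cout, 1, stride, 0, nm + ".downsample.conv", rng);
      bd.init(cout, nm + ".downsample.bn");
    }
  }

  fmat forward(const fmat& X, int& H, int& W, int B, bool train, bool cache) {
    fmat y = c1.forward(X, H, W, B, cache);
    y = b1.forward(y, train, cache);
    y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    if (cache) r1 = y;
    fmat y2 = c2.forward(y, c1.OH, c1.OW, B, cache);
    y2 = b2.forward(y2, train, cache);
    fmat skip;
    if (down) {
      skip = cd.forward(X, H, W, B, cache);
      skip = bd.forward(skip, train, cache);
    }
    y2 += down ? skip : X;
    y2.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    if (cache) out = y2;
    H = c1.OH; W = c1.OW;
    return y2;
  }

  fmat backward(const fmat& dY, bool want_dx = true) {
    fmat dpre = dY % conv_to<fmat>::from(out > 0.0f);
    // main branch
    fmat d = b2.backward(dpre);
    d = c2.backward(d);
    d %= conv_to<fmat>::from(r1 > 0.0f);
    d = b1.backward(d);
    fmat dX = c1.backward(d, want_dx || down || true);
    // skip branch
    if (down) {
      fmat ds = bd.backward(dpre);
      dX += cd.backward(ds);
    } else {
      dX += dpre;
    }
    return dX;
  }
};

// ---------------------------------------------------------------- Net -----
struct Net {
  int in_channels;
  float dropout;
  Conv stem;
  BatchNorm bn0;
  MaxPool pool;
  Block blocks[8];                     // 4 stages x 2
  Param fcw, fcb;
  std::mt19937 rng;
  long long adam_t = 0;

  // caches
  fmat stem_relu, gap_out, drop_mask;
  fmat stage_out[4];                   // outputs of stages 1..4 (cached fwd)
  int stage_h[4], stage_w[4];
  int curB = 0;

  void init(int cin, float drop, unsigned seed) {
    in_channels = cin; dropout = drop;
    rng.seed(seed);
    stem.init(cin, 64, 7, 2, 3, "stem.conv", rng);
    bn0.init(64, "stem.bn");
    const int chans[4] = {64, 128, 256, 512};
    int prev = 64;
    for (int s = 0; s < 4; ++s) {
      int stride = (s == 0) ? 1 : 2;
      blocks[2 * s].init(prev, chans[s], stride,
                         "layer" + std::to_string(s + 1) + ".0", rng);
      blocks[2 * s + 1].init(chans[s], chans[s], 1,
                             "layer" + std::to_string(s + 1) + ".1", rng);
      prev = chans[s];
    }
    fcw.init(1, 512, "fc.weight");
    fcb.init(1, 1, "fc.bias");
    // torch default linear init: U(-1/sqrt(fan_in), 1/sqrt(fan_in))
    std::uniform_real_distribution<float> ud(-1.0f / std::sqrt(512.0f),
                                             1.0f / std::sqrt(512.0f));
    for (uword i = 0; i < 512; ++i) fcw.w[i] = ud(rng);
    fcb.w[0] = ud(rng);
  }

  std::vector<Param*> params() {
    std::vector<Param*> p;
    p.push_back(&stem.W); p.push_back(&bn0.gamma); p.push_back(&bn0.beta);
    for (int i = 0; i < 8; ++i) {
      Block& b = blocks[i];
      p.push_back(&b.c1.W); p.push_back(&b.b1.gamma); p.push_back(&b.b1.beta);
      p.push_back(&b.c2.W); p.push_back(&b.b2.gamma); p.push_back(&b.b2.beta);
      if (b.down) {
        p.push_back(&b.cd.W); p.push_back(&b.bd.gamma); p.push_back(&b.bd.beta);
      }
    }
    p.push_back(&fcw); p.push_back(&fcb);
    return p;
  }

  std::vector<BatchNorm*> bns() {
    std::vector<BatchNorm*> v;
    v.push_back(&bn0);
    for (int i = 0; i < 8; ++i) {
      v.push_back(&blocks[i].b1);
      v.push_back(&blocks[i].b2);
      if (blocks[i].down) v.push_back(&blocks[i].bd);
    }
    return v;
  }

  // forward to logits (1 x B)
  frowvec forward(const fmat& X, int H, int W, int B, bool train, bool cache) {
    curB = B;
    fmat y = stem.forward(X, H, W, B, cache);
    y = bn0.forward(y, train, cache);
    y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    if (cache) stem_relu = y;
    int h = stem.OH, w = stem.OW;
    y = pool.forward(y, h, w, B, cache);
    h = pool.OH; w = pool.OW;
    for (int s = 0; s < 4; ++s) {
      y = blocks[2 * s].forward(y, h, w, B, train, cache);
      y = blocks[2 * s + 1].forward(y, h, w, B, train, cache);
      if (cache) { stage_out[s] = y; stage_h[s] = h; stage_w[s] = w; }
    }
    // global average pool
    const int HW = h * w;
    fmat g(512, B);
    for (int b = 0; b < B; ++b)
      g.col(b) = mean(y.cols(b * HW, (b + 1) * HW - 1), 1);
    if (cache) gap_out = g;
    // dropout
    if (train && dropout > 0.0f) {
      std::uniform_real_distribution<float> ud(0.0f, 1.0f);
      drop_mask.set_size(512, B);
      for (uword i = 0; i < drop_mask.n_elem; ++i)
        drop_mask[i] = (ud(rng) < dropout) ? 0.0f : 1.0f / (1.0f - dropout);
      g %= drop_mask;
    } else if (cache) {
      drop_mask.ones(512, B);
    }
    if (cache) gap_out = g;  // post-dropout input of fc
    frowvec z = fcw.w * g + fcb.w(0, 0);
    return z;
  }

  // backward from dlogit (1 x B); returns nothing (grads accumulated).
  // If capture_stage in 1..4, stops after computing the gradient at that
  // stage's output and stores it in *captured.
  void backward(const frowvec& dz, int capture_stage = 0, fmat* captured = nullptr) {
    int B = curB;
    fcw.g += dz * gap_out.t();
    fcb.g(0, 0) += accu(dz);
    fmat dg = fcw.w.t() * dz;            // 512 x B
    dg %= drop_mask;
    int h = stage_h[3], w = stage_w[3];
    const int HW = h * w;
    fmat dy(512, HW * B);
    for (int b = 0; b < B; ++b)
      dy.cols(b * HW, (b + 1) * HW - 1) = repmat(dg.col(b) / float(HW), 1, HW);
    for (int s = 3; s >= 0; --s) {
      if (capture_stage == s + 1) { *captured = dy; return; }
      dy = blocks[2 * s + 1].backward(dy);
      dy = blocks[2 * s].backward(dy);
    }
    dy = pool.backward(dy);
    dy %= conv_to<fmat>::from(stem_relu > 0.0f);
    dy = bn0.backward(dy);
    stem.backward(dy, false);
  }

  void zero_grads() {
    for (Param* p : params()) p->g.zeros();
  }

  void adam_step(double lr, double wd) {
    ++adam_t;
    double bc1 = 1.0 - std::pow(ADAM_B1, double(adam_t));
    double bc2 = 1.0 - std::pow(ADAM_B2, double(adam_t));
    for (Param* p : params()) {
      if (wd > 0) p->g += float(wd) * p->w;
      p->m = float(ADAM_B1) * p->m + float(1.0 - ADAM_B1) * p->g;
      p->v = float(ADAM_B2) * p->v + float(1.0 - ADAM_B2) * (p->g % p->g);
      fmat mh = p->m / float(bc1);
      fmat vh = p->v / float(bc2);
      p->w -= float(lr) * (mh / (sqrt(vh) + float(ADAM_EPS)));
    }
  }

  long long n_params() {
    long long n = 0;
    for (Param* p : params()) n += p->w.n_elem;
    return n;
  }
};

// ------------------------------------------------------------- helpers ----
static double sigmoidd(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Mann-Whitney AUC with ties counted 1/2
static double auc_mw(const std::vector<double>& s, const std::vector<int>& y) {
  size_t n = s.size();
  std::vector<size_t> ord(n);
  for (size_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) { return s[a] < s[b]; });
  std::vector<double> rank(n);
  size_t i = 0;
  while (i < n) {
    size_t j = i;
    while (j + 1 < n && s[ord[j + 1]] == s[ord[i]]) ++j;
    double r = 0.5 * (i + j) + 1.0;
    for (size_t t = i; t <= j; ++t) rank[ord[t]] = r;
    i = j + 1;
  }
  double rs = 0.0; long long np = 0;
  for (size_t t = 0; t < n; ++t) if (y[t] == 1) { rs += rank[t]; ++np; }
  long long nn = (long long)n - np;
  if (np == 0 || nn == 0) return NA_REAL;
  return (rs - np * (np + 1.0) / 2.0) / (double(np) * double(nn));
}

static fmat gather(const DataSet& d, const std::vector<int>& ids) {
  const int HW = d.H * d.W;
  fmat out(d.C, HW * ids.size());
  for (size_t k = 0; k < ids.size(); ++k)
    out.cols(k * HW, (k + 1) * HW - 1) = d.x.cols(ids[k] * HW, (ids[k] + 1) * HW - 1);
  return out;
}

static std::vector<double> predict_ids(Net& net, const DataSet& d,
                                       const std::vector<int>& ids, int bs) {
  std::vector<double> out(ids.size());
  for (size_t b0 = 0; b0 < ids.size(); b0 += bs) {
    size_t b1 = std::min(ids.size(), b0 + bs);
    std::vector<int> sub(ids.begin() + b0, ids.begin() + b1);
    fmat X = gather(d, sub);
    frowvec z = net.forward(X, d.H, d.W, int(sub.size()), false, false);
    for (size_t k = 0; k < sub.size(); ++k) out[b0 + k] = sigmoidd(z(k));
  }
  return out;
}

struct Snapshot {
  std::vector<fmat> w;
  std::vector<fvec> rm, rv;
};
static Snapshot snap(Net& net) {
  Snapshot s;
  for (Param* p : net.params()) s.w.push_back(p->w);
  for (BatchNorm* b : net.bns()) { s.rm.push_back(b->rmean); s.rv.push_back(b->rvar); }
  return s;
}
static void restore(Net& net, const Snapshot& s) {
  auto ps = net.params();
  for (size_t i = 0; i < ps.size(); ++i) ps[i]->w = s.w[i];
  auto bs = net.bns();
  for (size_t i = 0; i < bs.size(); ++i) { bs[i]->rmean = s.rm[i]; bs[i]->rvar = s.rv[i]; }
}

// ------------------------------------------------------------- exports ----

// [[Rcpp::export]]
SEXP nn_create(int in_channels, double dropout, int seed) {
  Net* net = new Net();
  net->init(in_channels, float(dropout), unsigned(seed));
  return Rcpp::XPtr<Net>(net, true);
}

// [[Rcpp::export]]
double nn_param_count(SEXP netp) {
  Rcpp::XPtr<Net> net(netp);
  return double(net->n_params());
}

// [[Rcpp::export]]
SEXP nn_data(Rcpp::NumericVector x, Rcpp::IntegerVector dims) {
  // dims = c(n, C, H, W); x ordered image-major, then channel, then y, x fastest
  DataSet* d = new DataSet();
  d->n = dims[0]; d->C = dims[1]; d->H = dims[2]; d->W = dims[3];
  const int HW = d->H * d->W;
  d->x.set_size(d->C, HW * d->n);
  const double* src = x.begin();
  for (int i = 0; i < d->n; ++i)
    for (int c = 0; c < d->C; ++c) {
      const double* s = src + (size_t(i) * d->C + c) * HW;
      for (int j = 0; j < HW; ++j) d->x(c, size_t(i) * HW + j) = float(s[j]);
    }
  return Rcpp::XPtr<DataSet>(d, true);
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_predict(SEXP netp, SEXP datap, Rcpp::IntegerVector idx,
                               int batch_size = 32) {
  Rcpp::XPtr<Net> net(netp);
  Rcpp::XPtr<DataSet> d(datap);
  std::vector<int> ids(idx.begin(), idx.end());
  for (int& i : ids) --i;
  std::vector<double> p = predict_ids(*net, *d, ids, batch_size);
  return Rcpp::NumericVector(p.begin(), p.end());
}

// [[Rcpp::export]]
Rcpp::List nn_train(SEXP netp, SEXP datap, Rcpp::NumericVector y,
                    Rcpp::IntegerVector idx_train, Rcpp::IntegerVector idx_val,
                    Rcpp::List cfg) {
  Rcpp::XPtr<Net> net(netp);
  Rcpp::XPtr<DataSet> d(datap);
  double lr = Rcpp::as<double>(cfg["lr"]);
  const double wd = Rcpp::as<double>(cfg["weight_decay"]);
  const int bs = Rcpp::as<int>(cfg["batch_size"]);
  const int max_epochs = Rcpp::as<int>(cfg["max_epochs"]);
  const double lr_factor = Rcpp::as<double>(cfg["lr_factor"]);
  const int lr_patience = Rcpp::as<int>(cfg["lr_patience"]);
  const double min_lr = Rcpp::as<double>(cfg["min_lr"]);
  const int stop_patience = Rcpp::as<int>(cfg["early_stop_patience"]);
  const int seed = Rcpp::as<int>(cfg["seed"]);

  std::vector<int> tr(idx_train.begin(), idx_train.end());
  std::vector<int> va(idx_val.begin(), idx_val.end());
  for (int& i : tr) --i;
  for (int& i : va) --i;
  std::vector<int> yva(va.size());
  for (size_t i = 0; i < va.size(); ++i) yva[i] = int(y[va[i]]);

  std::mt19937 shuf{static_cast<unsigned>(seed)};
  const int HW = d->H * d->W;

  double best_auc = -1.0;
  int best_epoch = 0, since_best = 0, lr_since = 0;
  Snapshot best;
  std::vector<double> tr_loss, tr_auc_hist, lr_hist;
  int epoch = 0;

  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(tr.begin(), tr.end(), shuf);
    double epoch_loss = 0.0;
    int nbatch = 0;
    for (size_t b0 = 0; b0 < tr.size(); b0 += bs) {
      size_t b1 = std::min(tr.size(), b0 + size_t(bs));
      if (b1 - b0 < 2 && tr.size() > 2) continue;  // BN needs >= 2
      std::vector<int> sub(tr.begin() + b0, tr.begin() + b1);
      int B = int(sub.size());
      fmat X = gather(*d, sub);
      frowvec z = net->forward(X, d->H, d->W, B, true, true);
      frowvec dz(B);
      double loss = 0.0;
      for (int k = 0; k < B; ++k) {
        double yk = y[sub[k]], zk = z(k);
        loss += std::max(zk, 0.0) - zk * yk + std::log1p(std::exp(-std::abs(zk)));
        dz(k) = float((sigmoidd(zk) - yk) / B);
      }
      loss /= B;
      net->zero_grads();
      net->backward(dz);
      net->adam_step(lr, wd);
      epoch_loss += loss; ++nbatch;
    }
    epoch_loss /= std::max(1, nbatch);

    std::vector<double> pv = predict_ids(*net, *d, va, bs);
    double vauc = auc_mw(pv, yva);
    tr_loss.push_back(epoch_loss);
    tr_auc_hist.push_back(vauc);
    lr_hist.push_back(lr);

    if (vauc > best_auc + 1e-6) {
      best_auc = vauc; best_epoch = epoch; since_best = 0; lr_since = 0;
      best = snap(*net);
    } else {
      ++since_best; ++lr_since;
    }
    if (lr_since >= lr_patience) {
      lr = std::max(min_lr, lr * lr_factor);
      lr_since = 0;
    }
    if (since_best >= stop_patience) break;
    Rcpp::checkUserInterrupt();
  }
  if (best_epoch > 0) restore(*net, best);

  return Rcpp::List::create(
      Rcpp::Named("best_val_auc") = best_auc,
      Rcpp::Named("epoch_of_best") = best_epoch,
      Rcpp::Named("epochs_run") = int(tr_loss.size()),
      Rcpp::Named("loss") = tr_loss,
      Rcpp::Named("val_auc") = tr_auc_hist,
      Rcpp::Named("lr") = lr_hist);
}

// Single optimization step on an externally assembled (augmented) batch.
// [[Rcpp::export]]
double nn_step(SEXP netp, Rcpp::NumericVector x, Rcpp::IntegerVector dims,
               Rcpp::NumericVector y, double lr, double weight_decay) {
  Rcpp::XPtr<Net> net(netp);
  int B = dims[0], C = dims[1], H = dims[2], W = dims[3];
  const int HW = H * W;
  fmat X(C, HW * B);
  const double* src = x.begin();
  for (int i = 0; i < B; ++i)
    for (int c = 0; c < C; ++c) {
      const double* s = src + (size_t(i) * C + c) * HW;
      for (int j = 0; j < HW; ++j) X(c, size_t(i) * HW + j) = float(s[j]);
    }
  frowvec z = net->forward(X, H, W, B, true, true);
  frowvec dz(B);
  double loss = 0.0;
  for (int k = 0; k < B; ++k) {
    double yk = y[k], zk = z(k);
    loss += std::max(zk, 0.0) - zk * yk + std::log1p(std::exp(-std::abs(zk)));
    dz(k) = float((sigmoidd(zk) - yk) / B);
  }
  loss /= B;
  net->zero_grads();
  net->backward(dz);
  net->adam_step(lr, weight_decay);
  return loss;
}

// Forward+backward without an optimizer step (for gradient checking).
// [[Rcpp::export]]
double nn_loss_backward(SEXP netp, Rcpp::NumericVector x, Rcpp::IntegerVector dims,
                        Rcpp::NumericVector y, bool do_backward) {
  Rcpp::XPtr<Net> net(netp);
  int B = dims[0], C = dims[1], H = dims[2], W = dims[3];
  const int HW = H * W;
  fmat X(C, HW * B);
  const double* src = x.begin();
  for (int i = 0; i < B; ++i)
    for (int c = 0; c < C; ++c) {
      const double* s = src + (size_t(i) * C + c) * HW;
      for (int j = 0; j < HW; ++j) X(c, size_t(i) * HW + j) = float(s[j]);
    }
  frowvec z = net->forward(X, H, W, B, true, do_backward);
  frowvec dz(B);
  double loss = 0.0;
  for (int k = 0; k < B; ++k) {
    double yk = y[k], zk = z(k);
    loss += std::max(zk, 0.0) - zk * yk + std::log1p(std::exp(-std::abs(zk)));
    dz(k) = float((sigmoidd(zk) - yk) / B);
  }
  loss /= B;
  if (do_backward) {
    net->zero_grads();
    net->backward(dz);
  }
  return loss;
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_predict_raw(SEXP netp, Rcpp::NumericVector x,
                                   Rcpp::IntegerVector dims) {
  Rcpp::XPtr<Net> net(netp);
  int B = dims[0], C = dims[1], H = dims[2], W = dims[3];
  const int HW = H * W;
  fmat X(C, HW * B);
  const double* src = x.begin();
  for (int i = 0; i < B; ++i)
    for (int c = 0; c < C; ++c) {
      const double* s = src + (size_t(i) * C + c) * HW;
      for (int j = 0; j < HW; ++j) X(c, size_t(i) * HW + j) = float(s[j]);
    }
  frowvec z = net->forward(X, H, W, B, false, false);
  Rcpp::NumericVector out(B);
  for (int k = 0; k < B; ++k) out[k] = sigmoidd(z(k));
  return out;
}

// [[Rcpp::export]]
Rcpp::List nn_get_weights(SEXP netp) {
  Rcpp::XPtr<Net> net(netp);
  Rcpp::List out;
  for (Param* p : net->params()) {
    Rcpp::NumericMatrix m(p->w.n_rows, p->w.n_cols);
    for (uword i = 0; i < p->w.n_elem; ++i) m[i] = p->w[i];
    out[p->name] = m;
  }
  auto bs = net->bns();
  for (size_t i = 0; i < bs.size(); ++i) {
    std::string base = "bnstat" + std::to_string(i);
    out[base + ".mean"] = Rcpp::NumericVector(bs[i]->rmean.begin(), bs[i]->rmean.end());
    out[base + ".var"] = Rcpp::NumericVector(bs[i]->rvar.begin(), bs[i]->rvar.end());
  }
  return out;
}

// [[Rcpp::export]]
void nn_set_weights(SEXP netp, Rcpp::List w) {
  Rcpp::XPtr<Net> net(netp);
  for (Param* p : net->params()) {
    Rcpp::NumericMatrix m = w[p->name];
    if (int(p->w.n_rows) != m.nrow() || int(p->w.n_cols) != m.ncol())
      Rcpp::stop("weight shape mismatch for %s", p->name.c_str());
    for (uword i = 0; i < p->w.n_elem; ++i) p->w[i] = float(m[i]);
  }
  auto bs = net->bns();
  for (size_t i = 0; i < bs.size(); ++i) {
    std::string base = "bnstat" + std::to_string(i);
    Rcpp::NumericVector rm = w[base + ".mean"], rv = w[base + ".var"];
    for (int c = 0; c < bs[i]->C; ++c) { bs[i]->rmean[c] = rm[c]; bs[i]->rvar[c] = rv[c]; }
  }
}

// [[Rcpp::export]]
Rcpp::List nn_get_grads(SEXP netp) {
  Rcpp::XPtr<Net> net(netp);
  Rcpp::List out;
  for (Param* p : net->params()) {
    Rcpp::NumericMatrix m(p->g.n_rows, p->g.n_cols);
    for (uword i = 0; i < p->g.n_elem; ++i) m[i] = p->g[i];
    out[p->name] = m;
  }
  return out;
}

// Grad-CAM at the output of stage `stage` (1..4). One map per image.
// [[Rcpp::export]]
Rcpp::List nn_gradcam(SEXP netp, Rcpp::NumericVector x, Rcpp::IntegerVector dims,
                      int stage) {
  Rcpp::XPtr<Net> net(netp);
  if (stage < 1 || stage > 4) Rcpp::stop("stage must be in 1..4");
  int B = dims[0], C = dims[1], H = dims[2], W = dims[3];
  const int HW = H * W;
  fmat X(C, HW * B);
  const double* src = x.begin();
  for (int i = 0; i < B; ++i)
    for (int c = 0; c < C; ++c) {
      const double* s = src + (size_t(i) * C + c) * HW;
      for (int j = 0; j < HW; ++j) X(c, size_t(i) * HW + j) = float(s[j]);
    }
  frowvec z = net->forward(X, H, W, B, false, true);
  frowvec dz(B, fill::ones);            // d(logit)/d(logit) = 1
  net->zero_grads();
  fmat dA;
  net->backward(dz, stage, &dA);
  net->zero_grads();
  const fmat& A = net->stage_out[stage - 1];
  int h = net->stage_h[stage - 1], w = net->stage_w[stage - 1];
  const int sHW = h * w;
  Rcpp::NumericVector heat(size_t(B) * sHW);
  for (int b = 0; b < B; ++b) {
    fvec alpha = mean(dA.cols(b * sHW, (b + 1) * sHW - 1), 1);
    frowvec cam = alpha.t() * A.cols(b * sHW, (b + 1) * sHW - 1);
    for (int j = 0; j < sHW; ++j)
      heat[size_t(b) * sHW + j] = std::max(0.0, double(cam(j)));
  }
  return Rcpp::List::create(Rcpp::Named("heat") = heat,
                            Rcpp::Named("h") = h, Rcpp::Named("w") = w,
                            Rcpp::Named("prob") = Rcpp::NumericVector::create(sigmoidd(z(0))));
}
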