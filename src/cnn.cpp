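// CNN engine: six 3x3 same-padding convolutions (two per pooling stage),
// 2x2 max pooling, two ReLU dense layers with inverted dropout and L1/L2
// weight penalties, and a sigmoid or softmax head, trained with Adam on
// cross-entropy. All randomness (init, shuffling, dropout) comes from an
// internal xorshift generator seeded explicitly, so runs are bit-stable
// for a fixed seed on a fixed BLAS configuration.
//
// Activations are stored one matrix per layer with shape (H*W) x C per
// sample, column-major pixel index p = r * W + c; convolutions are GEMMs
// against im2col buffers of shape (H*W) x (9*C_in).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// --- deterministic RNG (splitmix64 seeding + xorshift128+) ----------------
struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    auto splitmix = [](uint64_t &x) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      return z ^ (z >> 31);
    };
    uint64_t x = seed;
    s0 = splitmix(x);
    s1 = splitmix(x);
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  double norm() {  // Box-Muller, one value per call (second discarded)
    double u1 = 1.0 - unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  // Fisher-Yates shuffle of 0..n-1
  std::vector<int> permutation(int n) {
    std::vector<int> p(n);
    for (int i = 0; i < n; ++i) p[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif() * (i + 1));
      if (j > i) j = i;
      std::swap(p[i], p[j]);
    }
    return p;
  }
};

// --- im2col / col2im for 3x3 same padding ---------------------------------
// in: (H*W) x C activation; out: (H*W) x (9*C), block k (offset dy,dx) of
// channel c sits at column c*9 + k.
void im2col3(const arma::mat &in, int H, int W, arma::mat &out) {
  const int C = in.n_cols;
  out.zeros(H * W, 9 * C);
  for (int c = 0; c < C; ++c) {
    const double *src = in.colptr(c);
    int k = 0;
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        double *dst = out.colptr(c * 9 + k);
        int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
        int c0 = std::max(0, -dx), c1 = std::min(W, W - dx);
        for (int r = r0; r < r1; ++r) {
          const double *s = src + (r + dy) * W + (c0 + dx);
          double *d = dst + r * W + c0;
          std::copy(s, s + (c1 - c0), d);
        }
      }
    }
  }
}

// transpose of im2col3: scatter-add a (H*W) x (9*C) gradient back to (H*W) x C
void col2im3(const arma::mat &cols, int H, int W, arma::mat &out) {
  const int C = cols.n_cols / 9;
  out.zeros(H * W, C);
  for (int c = 0; c < C; ++c) {
    double *dst = out.colptr(c);
    int k = 0;
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        const double *src = cols.colptr(c * 9 + k);
        int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
        int c0 = std::max(0, -dx), c1 = std::min(W, W - dx);
        for (int r = r0; r < r1; ++r) {
          const double *s = src + r * W + c0;
          double *d = dst + (r + dy) * W + (c0 + dx);
          for (int cc = 0; cc < c1 - c0; ++cc) d[cc] += s[cc];
        }
      }
    }
  }
}

// 2x2 max pool, stride 2 (floor on odd dims); argmax recorded for backprop
void maxpool2(const arma::mat &in, int H, int W, arma::mat &out,
              arma::umat &arg) {
  const int C = in.n_cols, Ho = H / 2, Wo = W / 2;
  out.set_size(Ho * Wo, C);
  arg.set_size(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const double *src = in.colptr(c);
    for (int r = 0; r < Ho; ++r) {
      for (int q = 0; q < Wo; ++q) {
        int i00 = (2 * r) * W + 2 * q;
        int idx[4] = {i00, i00 + 1, i00 + W, i00 + W + 1};
        int best = idx[0];
        double bv = src[idx[0]];
        for (int k = 1; k < 4; ++k)
          if (src[idx[k]] > bv) { bv = src[idx[k]]; best = idx[k]; }
        out(r * Wo + q, c) = bv;
        arg(r * Wo + q, c) = best;
      }
    }
  }
}

struct LayerDims { int H, W, C; };

struct Net {
  int H0, W0, n_classes, d1, d2;
  arma::ivec filters;                 // 6 conv widths
  std::vector<arma::mat> Wc;          // (9*Cin) x Cout
  std::vector<arma::vec> bc;
  arma::mat Wd1, Wd2, Wo;
  arma::vec bd1, bd2, bo;
  std::vector<LayerDims> dims;        // input dims of each conv layer
  int flat;                           // flatten size
};

Net unpack(List model) {
  Net net;
  net.H0 = as<int>(model["H"]);
  net.W0 = as<int>(model["W"]);
  net.n_classes = as<int>(model["n_classes"]);
  net.filters = as<arma::ivec>(model["filters"]);
  List Wc = model["Wc"], bc = model["bc"];
  for (int i = 0; i < 6; ++i) {
    net.Wc.push_back(as<arma::mat>(Wc[i]));
    net.bc.push_back(as<arma::vec>(bc[i]));
  }
  net.Wd1 = as<arma::mat>(model["Wd1"]);
  net.bd1 = as<arma::vec>(model["bd1"]);
  net.Wd2 = as<arma::mat>(model["Wd2"]);
  net.bd2 = as<arma::vec>(model["bd2"]);
  net.Wo = as<arma::mat>(model["Wo"]);
  net.bo = as<arma::vec>(model["bo"]);
  net.d1 = net.Wd1.n_cols;
  net.d2 = net.Wd2.n_cols;
  int H = net.H0, W = net.W0, C = 1;
  for (int l = 0; l < 6; ++l) {
    net.dims.push_back({H, W, C});
    C = net.filters[l];
    if (l % 2 == 1) { H /= 2; W /= 2; }
  }
  net.flat = H * W * net.filters[5];
  return net;
}

// per-sample activation cache for backprop
struct Cache {
  std::vector<arma::mat> conv_in;   // input of each conv layer (post prev relu/pool)
  std::vector<arma::mat> conv_out;  // post-relu output of each conv layer
  std::vector<arma::mat> pool_out;
  std::vector<arma::umat> pool_arg;
  arma::vec flat, a1, a2;           // flatten, post-dropout dense activations
  arma::vec m1, m2;                 // dropout masks (already scaled)
};

// forward one sample; if train, applies dropout masks from rng
arma::vec forward(const Net &net, const arma::mat &x0, Cache *cache,
                  double dropout, Rng *rng) {
  arma::mat a = x0;  // (H*W) x 1
  arma::mat cols;
  int H = net.H0, W = net.W0;
  for (int l = 0; l < 6; ++l) {
    if (cache) cache->conv_in.push_back(a);
    im2col3(a, H, W, cols);
    arma::mat z = cols * net.Wc[l];
    z.each_row() += net.bc[l].t();
    z.transform([](double v) { return v > 0 ? v : 0.0; });
    if (cache) cache->conv_out.push_back(z);
    if (l % 2 == 1) {
      arma::mat pooled;
      arma::umat arg;
      maxpool2(z, H, W, pooled, arg);
      if (cache) { cache->pool_out.push_back(pooled); cache->pool_arg.push_back(arg); }
      a = pooled;
      H /= 2; W /= 2;
    } else {
      a = z;
    }
  }
  arma::vec f = arma::vectorise(a);
  arma::vec z1 = net.Wd1.t() * f + net.bd1;
  z1.transform([](double v) { return v > 0 ? v : 0.0; });
  arma::vec m1;
  if (rng && dropout > 0) {
    m1.set_size(z1.n_elem);
    for (arma::uword i = 0; i < m1.n_elem; ++i)
      m1[i] = rng->unif() >= dropout ? 1.0 / (1.0 - dropout) : 0.0;
    z1 %= m1;
  }
  arma::vec z2 = net.Wd2.t() * z1 + net.bd2;
  z2.transform([](double v) { return v > 0 ? v : 0.0; });
  arma::vec m2;
  if (rng && dropout > 0) {
    m2.set_size(z2.n_elem);
    for (arma::uword i = 0; i < m2.n_elem; ++i)
      m2[i] = rng->unif() >= dropout ? 1.0 / (1.0 - dropout) : 0.0;
    z2 %= m2;
  }
  arma::vec zo = net.Wo.t() * z2 + net.bo;
  arma::vec out;
  if (net.n_classes == 2) {
    out = 1.0 / (1.0 + arma::exp(-zo));  // single sigmoid unit
  } else {
    zo -= zo.max();
    out = arma::exp(zo);
    out /= arma::accu(out);
  }
  if (cache) {
    cache->flat = f;
    cache->a1 = z1; cache->a2 = z2;
    cache->m1 = m1; cache->m2 = m2;
  }
  return out;
}

struct Grads {
  std::vector<arma::mat> Wc{6};
  std::vector<arma::vec> bc{6};
  arma::mat Wd1, Wd2, Wo;
  arma::vec bd1, bd2, bo;
  void zero_like(const Net &net) {
    for (int l = 0; l < 6; ++l) {
      Wc[l].zeros(net.Wc[l].n_rows, net.Wc[l].n_cols);
      bc[l].zeros(net.bc[l].n_elem);
    }
    Wd1.zeros(net.Wd1.n_rows, net.Wd1.n_cols); bd1.zeros(net.bd1.n_elem);
    Wd2.zeros(net.Wd2.n_rows, net.Wd2.n_cols); bd2.zeros(net.bd2.n_elem);
    Wo.zeros(net.Wo.n_rows, net.Wo.n_cols);    bo.zeros(net.bo.n_elem);
  }
};

// backward for one sample; dout = dL/dlogits (sigmoid/softmax + CE)
void backward(const Net &net, const Cache &cache, const arma::mat &x0,
              const arma::vec &dout, Grads &g) {
  g.Wo += cache.a2 * dout.t();
  g.bo += dout;
  arma::vec d2 = net.Wo * dout;
  if (cache.m2.n_elem) d2 %= cache.m2;
  d2 %= arma::conv_to<arma::vec>::from(cache.a2 > 0);
  g.Wd2 += cache.a1 * d2.t();
  g.bd2 += d2;
  arma::vec d1 = net.Wd2 * d2;
  if (cache.m1.n_elem) d1 %= cache.m1;
  d1 %= arma::conv_to<arma::vec>::from(cache.a1 > 0);
  g.Wd1 += cache.flat * d1.t();
  g.bd1 += d1;
  arma::vec df = net.Wd1 * d1;

  int H = net.H0, W = net.W0;
  std::vector<LayerDims> outdims;  // dims of conv_out per layer
  for (int l = 0; l < 6; ++l) {
    outdims.push_back({H, W, (int)net.filters[l]});
    if (l % 2 == 1) { H /= 2; W /= 2; }
  }
  // gradient wrt last pooled activation
  arma::mat da = arma::reshape(df, (H * W), (int)net.filters[5]);
  arma::mat cols, dcols, dprev;
  for (int l = 5; l >= 0; --l) {
    const LayerDims od = outdims[l];
    arma::mat dz;
    if (l % 2 == 1) {  // un-pool through recorded argmax
      const arma::mat &pooled = cache.pool_out[l / 2];
      const arma::umat &arg = cache.pool_arg[l / 2];
      dz.zeros(od.H * od.W, od.C);
      for (int c = 0; c < od.C; ++c)
        for (arma::uword i = 0; i < pooled.n_rows; ++i)
          dz(arg(i, c), c) += da(i, c);
    } else {
      dz = da;
    }
    dz %= arma::conv_to<arma::mat>::from(cache.conv_out[l] > 0);
    im2col3(cache.conv_in[l], od.H, od.W, cols);
    g.Wc[l] += cols.t() * dz;
    g.bc[l] += arma::sum(dz, 0).t();
    if (l > 0) {
      dcols = dz * net.Wc[l].t();
      col2im3(dcols, od.H, od.W, dprev);
      da = dprev;
    }
  }
}

struct Adam {
  std::vector<arma::mat> mWc{6}, vWc{6};
  std::vector<arma::vec> mbc{6}, vbc{6};
  arma::mat mWd1, vWd1, mWd2, vWd2, mWo, vWo;
  arma::vec mbd1, vbd1, mbd2, vbd2, mbo, vbo;
  double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  long t = 0;
  void init(const Net &net) {
    for (int l = 0; l < 6; ++l) {
      mWc[l].zeros(net.Wc[l].n_rows, net.Wc[l].n_cols); vWc[l] = mWc[l];
      mbc[l].zeros(net.bc[l].n_elem); vbc[l] = mbc[l];
    }
    mWd1.zeros(net.Wd1.n_rows, net.Wd1.n_cols); vWd1 = mWd1;
    mWd2.zeros(net.Wd2.n_rows, net.Wd2.n_cols); vWd2 = mWd2;
    mWo.zeros(net.Wo.n_rows, net.Wo.n_cols);    vWo = mWo;
    mbd1.zeros(net.bd1.n_elem); vbd1 = mbd1;
    mbd2.zeros(net.bd2.n_elem); vbd2 = mbd2;
    mbo.zeros(net.bo.n_elem);   vbo = mbo;
  }
  template <class M>
  void step1(M &w, const M &gr, M &m, M &v, double lr) {
    m = b1 * m + (1 - b1) * gr;
    v = b2 * v + (1 - b2) * (gr % gr);
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  }
};

}  // namespace

// [[Rcpp::export(name = ".cnn_init")]]
List cnn_init_cpp(int H, int W, int n_classes, IntegerVector conv_filters,
                  int d1, int d2, int seed) {
  if (H < 8 || W < 8)
    stop("shape error: image must be at least 8 x 8 for three 2x2 poolings");
  Rng rng((uint64_t)seed * 0x51ed270bULL + 17ULL);
  List Wc(6), bc(6);
  int cin = 1, Hh = H, Ww = W;
  for (int l = 0; l < 6; ++l) {
    int cout = conv_filters[l];
    arma::mat w(9 * cin, cout);
    double sd = std::sqrt(2.0 / (9.0 * cin));  // He init
    for (auto &v : w) v = sd * rng.norm();
    Wc[l] = w;
    bc[l] = arma::vec(cout, arma::fill::zeros);
    cin = cout;
    if (l % 2 == 1) { Hh /= 2; Ww /= 2; }
  }
  int flat = Hh * Ww * conv_filters[5];
  auto dense = [&](int nin, int nout) {
    arma::mat w(nin, nout);
    double sd = std::sqrt(2.0 / nin);
    for (auto &v : w) v = sd * rng.norm();
    return w;
  };
  int nout = n_classes == 2 ? 1 : n_classes;
  // the head starts at zero so the untrained decision is maximally
  // uncertain (p = 0.5 / uniform softmax) and short runs stay
  // threshold-calibrated; gradients through it are nonzero immediately
  return List::create(
      _["H"] = H, _["W"] = W, _["n_classes"] = n_classes,
      _["filters"] = conv_filters,
      _["Wc"] = Wc, _["bc"] = bc,
      _["Wd1"] = dense(flat, d1), _["bd1"] = arma::vec(d1, arma::fill::zeros),
      _["Wd2"] = dense(d1, d2), _["bd2"] = arma::vec(d2, arma::fill::zeros),
      _["Wo"] = arma::mat(d2, nout, arma::fill::zeros),
      _["bo"] = arma::vec(nout, arma::fill::zeros));
}

// [[Rcpp::export(name = ".cnn_train")]]
List cnn_train_cpp(List model, arma::cube X, arma::ivec y, int epochs,
                   int batch_size, double lr, double l1, double l2,
                   double dropout, int seed) {
  Net net = unpack(model);
  const int n = X.n_slices;
  const int K = net.n_classes;
  Rng rng((uint64_t)seed * 0x9e3779b9ULL + 1ULL);
  Adam opt;
  opt.init(net);
  arma::vec loss_hist(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    std::vector<int> perm = rng.permutation(n);
    double ep_loss = 0;
    for (int start = 0; start < n; start += batch_size) {
      int bs = std::min(batch_size, n - start);
      Grads g;
      g.zero_like(net);
      double bloss = 0;
      for (int bi = 0; bi < bs; ++bi) {
        int i = perm[start + bi];
        arma::mat x0 = arma::vectorise(X.slice(i).t());  // row-major pixel order
        Cache cache;
        arma::vec p = forward(net, x0, &cache, dropout, &rng);
        arma::vec dout;
        if (K == 2) {
          double pi = std::min(std::max(p[0], 1e-12), 1.0 - 1e-12);
          double yi = (double)y[i];
          bloss += -(yi * std::log(pi) + (1 - yi) * std::log(1 - pi));
          dout = arma::vec{p[0] - yi};
        } else {
          double pi = std::max(p[y[i]], 1e-12);
          bloss += -std::log(pi);
          dout = p;
          dout[y[i]] -= 1.0;
        }
        backward(net, cache, x0, dout, g);
      }
      // mean gradient + L1/L2 penalties on the two dense layers
      double inv = 1.0 / bs;
      for (int l = 0; l < 6; ++l) { g.Wc[l] *= inv; g.bc[l] *= inv; }
      g.Wd1 = g.Wd1 * inv + l1 * arma::sign(net.Wd1) + 2.0 * l2 * net.Wd1;
      g.Wd2 = g.Wd2 * inv + l1 * arma::sign(net.Wd2) + 2.0 * l2 * net.Wd2;
      g.Wo *= inv;
      g.bd1 *= inv; g.bd2 *= inv; g.bo *= inv;

      opt.t += 1;
      for (int l = 0; l < 6; ++l) {
        opt.step1(net.Wc[l], g.Wc[l], opt.mWc[l], opt.vWc[l], lr);
        opt.step1(net.bc[l], g.bc[l], opt.mbc[l], opt.vbc[l], lr);
      }
      opt.step1(net.Wd1, g.Wd1, opt.mWd1, opt.vWd1, lr);
      opt.step1(net.bd1, g.bd1, opt.mbd1, opt.vbd1, lr);
      opt.step1(net.Wd2, g.Wd2, opt.mWd2, opt.vWd2, lr);
      opt.step1(net.bd2, g.bd2, opt.mbd2, opt.vbd2, lr);
      opt.step1(net.Wo, g.Wo, opt.mWo, opt.vWo, lr);
      opt.step1(net.bo, g.bo, opt.mbo, opt.vbo, lr);
      ep_loss += bloss;
    }
    loss_hist[ep] = ep_loss / n;
    if (ep % 10 == 9) Rcpp::checkUserInterrupt();
  }

  List Wc(6), bc(6);
  for (int l = 0; l < 6; ++l) { Wc[l] = net.Wc[l]; bc[l] = net.bc[l]; }
  List out = clone(model);
  out["Wc"] = Wc;
  out["bc"] = bc;
  out["Wd1"] = net.Wd1; out["bd1"] = net.bd1;
  out["Wd2"] = net.Wd2; out["bd2"] = net.bd2;
  out["Wo"] = net.Wo;   out["bo"] = net.bo;
  return List::create(_["model"] = out,
                      _["loss_history"] = NumericVector(loss_hist.begin(),
                                                        loss_hist.end()));
}

// [[Rcpp::export(name = ".cnn_predict")]]
arma::mat cnn_predict_cpp(List model, arma::cube X) {
  Net net = unpack(model);
  const int n = X.n_slices;
  const int nout = net.n_classes == 2 ? 1 : net.n_classes;
  arma::mat scores(n, nout);
  for (int i = 0; i < n; ++i) {
    arma::mat x0 = arma::vectorise(X.slice(i).t());  // row-major pixel order
    scores.row(i) = forward(net, x0, nullptr, 0.0, nullptr).t();
  }
  return scores;
}

// [[Rcpp::export(name = ".cnn_n_params")]]
List cnn_n_params_cpp(List model) {
  Net net = unpack(model);
  long conv = 0;
  for (int l = 0; l < 6; ++l)
    conv += (long)net.Wc[l].n_elem + (long)net.bc[l].n_elem;
  long dense = (long)net.Wd1.n_elem + net.bd1.n_elem +
               (long)net.Wd2.n_elem + net.bd2.n_elem +
               (long)net.Wo.n_elem + net.bo.n_elem;
  return List::create(_["conv"] = (double)conv, _["dense"] = (double)dense,
                      _["total"] = (double)(conv + dense));
}
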