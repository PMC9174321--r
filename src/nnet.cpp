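// Compact CPU conv-net engine: im2col convolutions (grouped/depthwise),
// per-channel affine normalization, ReLU/ReLU6/sigmoid, 2x2 max-pool,
// nearest-neighbour upsampling, Adam. Two fixed topologies are built on it:
// a U-net (nuclei segmentation, Dice loss) and an inverted-residual
// MobileNetV2-style per-tile scorer for multiple-instance learning.
// Everything is deterministic: weight init uses a private xorshift RNG and
// all computation is single-sample, single-threaded.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// ---------------------------------------------------------------- RNG ----
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed ? seed * 2685821657736338717ULL
                                        : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double norm() {
    double u1 = std::max(unif(), 1e-300), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

// --------------------------------------------------------------- Adam ----
struct Param {
  mat W, G, m, v;
  long t = 0;
  void init(int r, int c) { W.zeros(r, c); G.zeros(r, c); }
  // Adam on the data gradient; the L2 penalty's gradient 2*alpha*w is
  // applied as decoupled weight decay (AdamW style) so that Adam's
  // per-parameter normalization cannot inflate the decay term for
  // weights with small data gradients.
  void step(double lr, double l2) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    if (l2 > 0) W -= lr * 2.0 * l2 * W;
    if (m.n_elem == 0) { m.zeros(size(W)); v.zeros(size(W)); }
    ++t;
    m = b1 * m + (1 - b1) * G;
    v = b2 * v + (1 - b2) * (G % G);
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    W -= lr * (m / c1) / (sqrt(v / c2) + eps);
    G.zeros();
  }
  void reset_opt() { m.reset(); v.reset(); t = 0; }
};

// ------------------------------------------------------------- im2col ----
static void im2col(const cube& x, int c0, int cn, int k, int stride, int pad,
                   int Ho, int Wo, mat& col) {
  const int Hi = x.n_rows, Wi = x.n_cols;
  col.set_size(cn * k * k, Ho * Wo);
  for (int c = 0; c < cn; ++c) {
    const mat& ch = x.slice(c0 + c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = c * k * k + kj * k + ki;
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride - pad + kj;
          const int cc = oj * Ho;
          if (ij < 0 || ij >= Wi) {
            for (int oi = 0; oi < Ho; ++oi) col(r, cc + oi) = 0.0;
            continue;
          }
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride - pad + ki;
            col(r, cc + oi) = (ii < 0 || ii >= Hi) ? 0.0 : ch(ii, ij);
          }
        }
      }
    }
  }
}

static void col2im(const mat& col, cube& gx, int c0, int cn, int k, int stride,
                   int pad, int Ho, int Wo) {
  const int Hi = gx.n_rows, Wi = gx.n_cols;
  for (int c = 0; c < cn; ++c) {
    mat& ch = gx.slice(c0 + c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = c * k * k + kj * k + ki;
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride - pad + kj;
          if (ij < 0 || ij >= Wi) continue;
          const int cc = oj * Ho;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride - pad + ki;
            if (ii >= 0 && ii < Hi) ch(ii, ij) += col(r, cc + oi);
          }
        }
      }
    }
  }
}

// --------------------------------------------------------------- Conv ----
struct Conv {
  int cin = 0, cout = 0, k = 3, stride = 1, pad = 1, groups = 1;
  Param W;  // cout x (cin/groups * k*k); rows of group g: [g*coutg, (g+1)*coutg)
  Param b;  // cout x 1
  std::vector<mat> cols;  // cached per-group im2col matrices
  int Hi = 0, Wi = 0, Ho = 0, Wo = 0;

  void setup(int ci, int co, int kk, int st, int gr, XRng& rng) {
    cin = ci; cout = co; k = kk; stride = st; pad = (kk - 1) / 2; groups = gr;
    W.init(co, (ci / gr) * kk * kk);
    b.init(co, 1);
    const double sd = std::sqrt(2.0 / ((ci / gr) * kk * kk));
    for (uword i = 0; i < W.W.n_elem; ++i) W.W(i) = sd * rng.norm();
  }

  cube forward(const cube& x, bool cache) {
    Hi = x.n_rows; Wi = x.n_cols;
    Ho = (Hi + 2 * pad - k) / stride + 1;
    Wo = (Wi + 2 * pad - k) / stride + 1;
    cube y(Ho, Wo, cout);
    const int cing = cin / groups, coutg = cout / groups;
    if (cache) cols.assign(groups, mat());
    mat colbuf;
    for (int g = 0; g < groups; ++g) {
      mat& col = cache ? cols[g] : colbuf;
      im2col(x, g * cing, cing, k, stride, pad, Ho, Wo, col);
      mat Y = W.W.rows(g * coutg, (g + 1) * coutg - 1) * col;
      Y.each_col() += b.W.col(0).subvec(g * coutg, (g + 1) * coutg - 1);
      for (int c = 0; c < coutg; ++c)
        y.slice(g * coutg + c) = reshape(Y.row(c), Ho, Wo);
    }
    return y;
  }

  cube backward(const cube& gy) {
    const int cing = cin / groups, coutg = cout / groups;
    cube gx(Hi, Wi, cin, fill::zeros);
    for (int g = 0; g < groups; ++g) {
      mat Gy(coutg, Ho * Wo);
      for (int c = 0; c < coutg; ++c)
        Gy.row(c) = reshape(gy.slice(g * coutg + c), 1, Ho * Wo);
      W.G.rows(g * coutg, (g + 1) * coutg - 1) += Gy * cols[g].t();
      b.G.col(0).subvec(g * coutg, (g + 1) * coutg - 1) += sum(Gy, 1);
      mat dcol = W.W.rows(g * coutg, (g + 1) * coutg - 1).t() * Gy;
      col2im(dcol, gx, g * cing, cing, k, stride, pad, Ho, Wo);
    }
    cols.clear();
    return gx;
  }
};

// ------------------------------------------------------------- Affine ----
// Per-channel scale + shift (normalization-layer parameters).
struct Affine {
  Param g, b;
  cube xc;
  void setup(int c) { g.init(c, 1); g.W.ones(); b.init(c, 1); }
  cube forward(const cube& x, bool cache) {
    if (cache) xc = x;
    cube y = x;
    for (uword c = 0; c < x.n_slices; ++c)
      y.slice(c) = g.W(c) * x.slice(c) + b.W(c);
    return y;
  }
  cube backward(const cube& gy) {
    cube gx = gy;
    for (uword c = 0; c < gy.n_slices; ++c) {
      g.G(c) += accu(gy.slice(c) % xc.slice(c));
      b.G(c) += accu(gy.slice(c));
      gx.slice(c) = g.W(c) * gy.slice(c);
    }
    xc.reset();
    return gx;
  }
};

// -------------------------------------------------------- activations ----
struct Act {  // mode 0 = ReLU, 1 = ReLU6
  int mode = 0;
  cube mask;
  cube forward(const cube& x, bool cache) {
    cube y = clamp(x, 0.0, mode == 1 ? 6.0 : datum::inf);
    if (cache) {
      mask = conv_to<cube>::from(x > 0);
      if (mode == 1) mask %= conv_to<cube>::from(x < 6);
    }
    return y;
  }
  cube backward(const cube& gy) { cube gx = gy % mask; mask.reset(); return gx; }
};

struct MaxPool {
  ucube idx;
  int Hi = 0, Wi = 0;
  cube forward(const cube& x, bool cache) {
    Hi = x.n_rows; Wi = x.n_cols;
    const int Ho = Hi / 2, Wo = Wi / 2;
    cube y(Ho, Wo, x.n_slices);
    if (cache) idx.set_size(Ho, Wo, x.n_slices);
    for (uword c = 0; c < x.n_slices; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double best = -datum::inf; int bi = 0;
          for (int d = 0; d < 4; ++d) {
            double v = x(2 * i + d % 2, 2 * j + d / 2, c);
            if (v > best) { best = v; bi = d; }
          }
          y(i, j, c) = best;
          if (cache) idx(i, j, c) = bi;
        }
    return y;
  }
  cube backward(const cube& gy) {
    cube gx(Hi, Wi, gy.n_slices, fill::zeros);
    for (uword c = 0; c < gy.n_slices; ++c)
      for (uword j = 0; j < gy.n_cols; ++j)
        for (uword i = 0; i < gy.n_rows; ++i) {
          const int d = idx(i, j, c);
          gx(2 * i + d % 2, 2 * j + d / 2, c) += gy(i, j, c);
        }
    idx.reset();
    return gx;
  }
};

struct Upsample {  // nearest neighbour, factor 2
  cube forward(const cube& x) {
    cube y(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
    for (uword c = 0; c < x.n_slices; ++c)
      for (uword j = 0; j < x.n_cols; ++j)
        for (uword i = 0; i < x.n_rows; ++i) {
          const double v = x(i, j, c);
          y(2 * i, 2 * j, c) = v; y(2 * i + 1, 2 * j, c) = v;
          y(2 * i, 2 * j + 1, c) = v; y(2 * i + 1, 2 * j + 1, c) = v;
        }
    return y;
  }
  cube backward(const cube& gy) {
    cube gx(gy.n_rows / 2, gy.n_cols / 2, gy.n_slices);
    for (uword c = 0; c < gy.n_slices; ++c)
      for (uword j = 0; j < gx.n_cols; ++j)
        for (uword i = 0; i < gx.n_rows; ++i)
          gx(i, j, c) = gy(2 * i, 2 * j, c) + gy(2 * i + 1, 2 * j, c) +
                        gy(2 * i, 2 * j + 1, c) + gy(2 * i + 1, 2 * j + 1, c);
    return gx;
  }
};

static cube concat_ch(const cube& a, const cube& b) {
  cube y(a.n_rows, a.n_cols, a.n_slices + b.n_slices);
  y.slices(0, a.n_slices - 1) = a;
  y.slices(a.n_slices, y.n_slices - 1) = b;
  return y;
}

// -------------------------------------------------------------- U-net ----
struct UNet {
  int depth, base, cin;
  std::vector<Conv> e1, e2, d1, d2;
  std::vector<Act> re1, re2, rd1, rd2;
  std::vector<MaxPool> pools;
  std::vector<Upsample> ups;
  Conv m1, m2, fin;
  Act rm1, rm2;
  std::vector<cube> skips;
  mat out;  // sigmoid probabilities

  UNet(int depth_, int base_, int cin_, uint64_t seed)
      : depth(depth_), base(base_), cin(cin_) {
    XRng rng(seed);
    e1.resize(depth); e2.resize(depth); d1.resize(depth); d2.resize(depth);
    re1.resize(depth); re2.resize(depth); rd1.resize(depth); rd2.resize(depth);
    pools.resize(depth); ups.resize(depth); skips.resize(depth);
    for (int l = 0; l < depth; ++l) {
      const int ci = (l == 0) ? cin : (base << (l - 1));
      const int co = base << l;
      e1[l].setup(ci, co, 3, 1, 1, rng);
      e2[l].setup(co, co, 3, 1, 1, rng);
    }
    const int cb = base << (depth - 1), cm = base << depth;
    m1.setup(cb, cm, 3, 1, 1, rng);
    m2.setup(cm, cm, 3, 1, 1, rng);
    for (int l = depth - 1; l >= 0; --l) {
      const int cs = base << l;
      const int cu = (l == depth - 1) ? cm : (base << (l + 1));
      d1[l].setup(cs + cu, cs, 3, 1, 1, rng);
      d2[l].setup(cs, cs, 3, 1, 1, rng);
    }
    fin.setup(base, 1, 1, 1, 1, rng);
  }

  template <typename F> void each_param(F f) {
    for (int l = 0; l < depth; ++l) {
      f(e1[l].W); f(e1[l].b); f(e2[l].W); f(e2[l].b);
    }
    f(m1.W); f(m1.b); f(m2.W); f(m2.b);
    for (int l = depth - 1; l >= 0; --l) {
      f(d1[l].W); f(d1[l].b); f(d2[l].W); f(d2[l].b);
    }
    f(fin.W); f(fin.b);
  }

  mat forward(const cube& x, bool cache) {
    cube cur = x;
    for (int l = 0; l < depth; ++l) {
      cur = re1[l].forward(e1[l].forward(cur, cache), cache);
      cur = re2[l].forward(e2[l].forward(cur, cache), cache);
      skips[l] = cur;  // kept for the decoder's skip connection
      cur = pools[l].forward(cur, cache);
    }
    cur = rm1.forward(m1.forward(cur, cache), cache);
    cur = rm2.forward(m2.forward(cur, cache), cache);
    for (int l = depth - 1; l >= 0; --l) {
      cur = ups[l].forward(cur);
      cur = concat_ch(skips[l], cur);
      cur = rd1[l].forward(d1[l].forward(cur, cache), cache);
      cur = rd2[l].forward(d2[l].forward(cur, cache), cache);
    }
    cube o = fin.forward(cur, cache);
    out = 1.0 / (1.0 + exp(-o.slice(0)));
    return out;
  }

  void backward(const mat& gprob) {
    mat go = gprob % out % (1.0 - out);
    cube g(go.n_rows, go.n_cols, 1);
    g.slice(0) = go;
    g = fin.backward(g);
    std::vector<cube> gskip(depth);
    for (int l = 0; l < depth; ++l) {
      g = d1[l].backward(rd1[l].backward(d2[l].backward(rd2[l].backward(g))));
      const int cs = base << l;
      gskip[l] = g.slices(0, cs - 1);
      g = ups[l].backward(g.slices(cs, g.n_slices - 1));
    }
    g = m1.backward(rm1.backward(m2.backward(rm2.backward(g))));
    for (int l = depth - 1; l >= 0; --l) {
      g = pools[l].backward(g);
      g += gskip[l];
      g = e1[l].backward(re1[l].backward(e2[l].backward(re2[l].backward(g))));
    }
  }

  void step(double lr) { each_param([lr](Param& p) { p.step(lr, 0.0); }); }
};

static cube as_cube(const NumericVector& a) {
  IntegerVector d = a.attr("dim");
  if (d.size() == 2) {
    cube x(d[0], d[1], 1);
    std::copy(a.begin(), a.end(), x.memptr());
    return x;
  }
  cube x(d[0], d[1], d[2]);
  std::copy(a.begin(), a.end(), x.memptr());
  return x;
}

// [[Rcpp::export(name = ".unet_create")]]
SEXP unet_create(int depth, int base_channels, int in_channels, double seed) {
  XPtr<UNet> p(new UNet(depth, base_channels, in_channels, (uint64_t)seed),
               true);
  return p;
}

// [[Rcpp::export(name = ".unet_nparams")]]
double unet_nparams(SEXP ptr) {
  XPtr<UNet> p(ptr);
  double n = 0;
  p->each_param([&n](Param& q) { n += q.W.n_elem; });
  return n;
}

// [[Rcpp::export(name = ".unet_get_weights")]]
NumericVector unet_get_weights(SEXP ptr) {
  XPtr<UNet> p(ptr);
  std::vector<double> w;
  p->each_param([&w](Param& q) {
    w.insert(w.end(), q.W.begin(), q.W.end());
  });
  return NumericVector(w.begin(), w.end());
}

// [[Rcpp::export(name = ".unet_set_weights")]]
void unet_set_weights(SEXP ptr, NumericVector w) {
  XPtr<UNet> p(ptr);
  size_t off = 0;
  p->each_param([&](Param& q) {
    if (off + q.W.n_elem > (size_t)w.size()) stop("weight vector too short");
    std::copy(w.begin() + off, w.begin() + off + q.W.n_elem, q.W.memptr());
    off += q.W.n_elem;
  });
  if (off != (size_t)w.size()) stop("weight vector length mismatch");
}

// [[Rcpp::export(name = ".unet_predict")]]
NumericMatrix unet_predict(SEXP ptr, NumericVector img) {
  XPtr<UNet> p(ptr);
  mat y = p->forward(as_cube(img), false);
  return wrap(y);
}

// Dice loss on the sigmoid output and one Adam step.
// [[Rcpp::export(name = ".unet_train_step")]]
double unet_train_step(SEXP ptr, NumericVector img, NumericMatrix mask,
                       double lr, double eps) {
  XPtr<UNet> p(ptr);
  mat y = as<mat>(mask);
  mat pr = p->forward(as_cube(img), true);
  const double A = accu(pr % y) + eps;
  const double B = accu(pr) + accu(y) + eps;
  const double loss = 1.0 - 2.0 * A / B;
  mat g = -2.0 * (y * B - A) / (B * B);  // d loss / d p
  p->backward(g);
  p->step(lr);
  return loss;
}

// ------------------------------------------- inverted-residual scorer ----
struct Block {
  bool has_expand = true, res = false;
  Conv cexp, cdw, cpr;
  Affine aexp, adw, apr;
  Act rexp, rdw;
  cube xin;

  void setup(int ci, int co, int t, int stride, XRng& rng) {
    const int hid = ci * t;
    has_expand = (t != 1);
    res = (stride == 1 && ci == co);
    if (has_expand) {
      cexp.setup(ci, hid, 1, 1, 1, rng);
      aexp.setup(hid);
    }
    rexp.mode = 1; rdw.mode = 1;
    cdw.setup(hid, hid, 3, stride, hid, rng);
    adw.setup(hid);
    cpr.setup(hid, co, 1, 1, 1, rng);
    apr.setup(co);
  }

  cube forward(const cube& x, bool cache) {
    if (cache && res) xin = x;
    cube h = x;
    if (has_expand)
      h = rexp.forward(aexp.forward(cexp.forward(h, cache), cache), cache);
    h = rdw.forward(adw.forward(cdw.forward(h, cache), cache), cache);
    h = apr.forward(cpr.forward(h, cache), cache);
    if (res) h += x;
    return h;
  }

  cube backward(const cube& gy) {
    cube g = cpr.backward(apr.backward(gy));
    g = cdw.backward(adw.backward(rdw.backward(g)));
    if (has_expand) g = cexp.backward(aexp.backward(rexp.backward(g)));
    if (res) g += gy;
    xin.reset();
    return g;
  }

  template <typename F> void each_param(F f) {
    if (has_expand) { f(cexp.W); f(cexp.b); f(aexp.g); f(aexp.b); }
    f(cdw.W); f(cdw.b); f(adw.g); f(adw.b);
    f(cpr.W); f(cpr.b); f(apr.g); f(apr.b);
  }
};

struct Backbone {
  Conv stem, head;
  Affine astem, ahead;
  Act rstem, rhead;
  std::vector<Block> blocks;
  Param fcw, fcb;
  cube headout;
  vec gap;

  Backbone(int in_ch, int stem_c, const imat& spec, int head_c,
           uint64_t seed) {
    XRng rng(seed);
    rstem.mode = 1; rhead.mode = 1;
    stem.setup(in_ch, stem_c, 3, 2, 1, rng);
    astem.setup(stem_c);
    int prev = stem_c;
    for (uword r = 0; r < spec.n_rows; ++r) {
      const int t = spec(r, 0), c = spec(r, 1), n = spec(r, 2), s = spec(r, 3);
      for (int rep = 0; rep < n; ++rep) {
        Block b;
        b.setup(prev, c, t, rep == 0 ? s : 1, rng);
        blocks.push_back(b);
        prev = c;
      }
    }
    head.setup(prev, head_c, 1, 1, 1, rng);
    ahead.setup(head_c);
    fcw.init(head_c, 1);
    const double sd = std::sqrt(1.0 / head_c);
    for (int i = 0; i < head_c; ++i) fcw.W(i) = sd * rng.norm();
    fcb.init(1, 1);
  }

  template <typename F> void each_param(F f) {
    f(stem.W); f(stem.b); f(astem.g); f(astem.b);
    for (auto& b : blocks) b.each_param(f);
    f(head.W); f(head.b); f(ahead.g); f(ahead.b);
    f(fcw); f(fcb);
  }

  double forward(const cube& x, bool cache) {
    cube h = rstem.forward(astem.forward(stem.forward(x, cache), cache), cache);
    for (auto& b : blocks) h = b.forward(h, cache);
    h = rhead.forward(ahead.forward(head.forward(h, cache), cache), cache);
    if (cache) headout = h;
    gap.set_size(h.n_slices);
    for (uword c = 0; c < h.n_slices; ++c) gap(c) = mean(mean(h.slice(c)));
    return dot(fcw.W.col(0), gap) + fcb.W(0, 0);
  }

  void backward(double ds) {
    fcw.G.col(0) += ds * gap;
    fcb.G(0, 0) += ds;
    cube g(headout.n_rows, headout.n_cols, headout.n_slices);
    const double inv = 1.0 / (headout.n_rows * headout.n_cols);
    for (uword c = 0; c < g.n_slices; ++c)
      g.slice(c).fill(ds * fcw.W(c, 0) * inv);
    g = head.backward(ahead.backward(rhead.backward(g)));
    for (int i = (int)blocks.size() - 1; i >= 0; --i) g = blocks[i].backward(g);
    stem.backward(astem.backward(rstem.backward(g)));
    headout.reset();
  }

  void step(double lr, double l2) {
    each_param([lr, l2](Param& p) { p.step(lr, l2); });
  }
};

// [[Rcpp::export(name = ".bb_create")]]
SEXP bb_create(int in_channels, int stem_channels, IntegerMatrix block_spec,
               int head_channels, double seed) {
  imat spec(block_spec.nrow(), block_spec.ncol());
  for (int i = 0; i < block_spec.nrow(); ++i)
    for (int j = 0; j < block_spec.ncol(); ++j) spec(i, j) = block_spec(i, j);
  XPtr<Backbone> p(new Backbone(in_channels, stem_channels, spec,
                                head_channels, (uint64_t)seed), true);
  return p;
}

// [[Rcpp::export(name = ".bb_nparams")]]
double bb_nparams(SEXP ptr) {
  XPtr<Backbone> p(ptr);
  double n = 0;
  p->each_param([&n](Param& q) { n += q.W.n_elem; });
  return n;
}

// [[Rcpp::export(name = ".bb_get_weights")]]
NumericVector bb_get_weights(SEXP ptr) {
  XPtr<Backbone> p(ptr);
  std::vector<double> w;
  p->each_param([&w](Param& q) {
    w.insert(w.end(), q.W.begin(), q.W.end());
  });
  return NumericVector(w.begin(), w.end());
}

// [[Rcpp::export(name = ".bb_set_weights")]]
void bb_set_weights(SEXP ptr, NumericVector w) {
  XPtr<Backbone> p(ptr);
  size_t off = 0;
  p->each_param([&](Param& q) {
    if (off + q.W.n_elem > (size_t)w.size()) stop("weight vector too short");
    std::copy(w.begin() + off, w.begin() + off + q.W.n_elem, q.W.memptr());
    off += q.W.n_elem;
  });
  if (off != (size_t)w.size()) stop("weight vector length mismatch");
}

// [[Rcpp::export(name = ".bb_l2")]]
double bb_l2(SEXP ptr) {
  XPtr<Backbone> p(ptr);
  double s = 0;
  p->each_param([&s](Param& q) { s += accu(q.W % q.W); });
  return s;
}

// [[Rcpp::export(name = ".bb_forward")]]
NumericVector bb_forward(SEXP ptr, List tiles) {
  XPtr<Backbone> p(ptr);
  NumericVector out(tiles.size());
  for (int i = 0; i < tiles.size(); ++i)
    out[i] = p->forward(as_cube(tiles[i]), false);
  return out;
}

// One bag: accumulate per-tile gradients (dL/ds_i supplied by the caller)
// and take a single Adam step with L2 weight penalty.
// [[Rcpp::export(name = ".bb_train_bag")]]
NumericVector bb_train_bag(SEXP ptr, List tiles, NumericVector dscore,
                           double lr, double l2_alpha) {
  XPtr<Backbone> p(ptr);
  NumericVector scores(tiles.size());
  for (int i = 0; i < tiles.size(); ++i) {
    scores[i] = p->forward(as_cube(tiles[i]), true);
    p->backward(dscore[i]);
  }
  p->step(lr, l2_alpha);
  return scores;
}
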