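// BrainCDNet training engine.
//
// Feature-map layout: a batch is Cube<eT>(H*W, C, B); pixel index p = h + H*w
// matches R's column-major array (h, w, c, b), so R arrays map onto cubes
// without permutation. Convolutions are im2col + GEMM with TensorFlow-style
// "same" padding (extra padding goes to the bottom/right); pooling is valid
// 2x2 stride 2. The engine is templated so the training build runs in single
// precision while gradient checks run in double.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
// [[Rcpp::plugins(cpp17)]]

using namespace arma;
using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;
using Rcpp::IntegerVector;
using Rcpp::CharacterVector;
using Rcpp::Named;
using Rcpp::stop;

// ---------------------------------------------------------------- activations

static const double SELU_LAMBDA = 1.0507009873554804934193349852946;
static const double SELU_ALPHA  = 1.6732632423543772848170429916717;

template <typename eT> inline eT selu_one(eT x) {
  return x > eT(0) ? eT(SELU_LAMBDA) * x
                   : eT(SELU_LAMBDA * SELU_ALPHA) * (std::exp(x) - eT(1));
}
template <typename eT> inline eT selu_grad_one(eT x) {
  return x > eT(0) ? eT(SELU_LAMBDA) : eT(SELU_LAMBDA * SELU_ALPHA) * std::exp(x);
}
template <typename eT> inline eT gelu_one(eT x) {
  return eT(0.5) * x * (eT(1) + std::erf(x / eT(M_SQRT2)));
}
template <typename eT> inline eT gelu_grad_one(eT x) {
  const eT phi = std::exp(eT(-0.5) * x * x) / eT(std::sqrt(2.0 * M_PI));
  return eT(0.5) * (eT(1) + std::erf(x / eT(M_SQRT2))) + x * phi;
}

template <typename eT>
void act_apply(const Cube<eT>& z, Cube<eT>& out, bool gelu) {
  out.set_size(size(z));
  const eT* zi = z.memptr(); eT* oi = out.memptr();
  const uword n = z.n_elem;
  if (gelu) for (uword i = 0; i < n; ++i) oi[i] = gelu_one(zi[i]);
  else      for (uword i = 0; i < n; ++i) oi[i] = selu_one(zi[i]);
}

// dz = dy .* act'(z)
template <typename eT>
void act_backprop(const Cube<eT>& z, Cube<eT>& dy, bool gelu) {
  eT* d = dy.memptr(); const eT* zi = z.memptr();
  const uword n = z.n_elem;
  if (gelu) for (uword i = 0; i < n; ++i) d[i] *= gelu_grad_one(zi[i]);
  else      for (uword i = 0; i < n; ++i) d[i] *= selu_grad_one(zi[i]);
}

// ---------------------------------------------------------------- convolution

// "same" padding at the leading edge (TF convention: floor(total/2))
inline int same_pad_beg(int in, int k, int stride) {
  int out = (in + stride - 1) / stride;
  int total = std::max((out - 1) * stride + k - in, 0);
  return total / 2;
}

template <typename eT>
struct Param {
  Mat<eT> val, g, m, v;
  std::string name;
  void init(uword r, uword c, const std::string& nm) {
    val.zeros(r, c); g.zeros(r, c); m.zeros(r, c); v.zeros(r, c); name = nm;
  }
};

template <typename eT>
struct ConvLayer {
  int kh, kw, stride, cin, cout, H, W, Ho, Wo, padh, padw;
  Param<eT> Wm;  // (K x cout), K = cin*kh*kw, k = (c*kh + ki)*kw + kj
  Param<eT> b;   // (cout x 1)
  void configure(int kh_, int kw_, int stride_, int cin_, int cout_,
                 int H_, int W_, const std::string& nm) {
    kh = kh_; kw = kw_; stride = stride_; cin = cin_; cout = cout_;
    H = H_; W = W_;
    Ho = (H + stride - 1) / stride; Wo = (W + stride - 1) / stride;
    if (stride == 1) { Ho = H; Wo = W; }
    padh = same_pad_beg(H, kh, stride); padw = same_pad_beg(W, kw, stride);
    Wm.init(uword(cin) * kh * kw, cout, nm + ".W");
    b.init(cout, 1, nm + ".b");
  }

  void im2col(const Mat<eT>& Xs, Mat<eT>& col) const {
    col.set_size(uword(Ho) * Wo, uword(cin) * kh * kw);
    for (int c = 0; c < cin; ++c) {
      const eT* xc = Xs.colptr(c);
      for (int ki = 0; ki < kh; ++ki) {
        for (int kj = 0; kj < kw; ++kj) {
          eT* dst = col.colptr((uword(c) * kh + ki) * kw + kj);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - padw + kj;
            eT* d = dst + uword(wo) * Ho;
            if (wi < 0 || wi >= W) {
              std::fill(d, d + Ho, eT(0));
              continue;
            }
            const eT* src = xc + uword(wi) * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - padh + ki;
              d[ho] = (hi < 0 || hi >= H) ? eT(0) : src[hi];
            }
          }
        }
      }
    }
  }

  void col2im_add(const Mat<eT>& dcol, Mat<eT>& dXs) const {
    for (int c = 0; c < cin; ++c) {
      eT* xc = dXs.colptr(c);
      for (int ki = 0; ki < kh; ++ki) {
        for (int kj = 0; kj < kw; ++kj) {
          const eT* src = dcol.colptr((uword(c) * kh + ki) * kw + kj);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - padw + kj;
            if (wi < 0 || wi >= W) continue;
            const eT* s = src + uword(wo) * Ho;
            eT* x = xc + uword(wi) * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - padh + ki;
              if (hi >= 0 && hi < H) x[hi] += s[ho];
            }
          }
        }
      }
    }
  }

  void forward(const Cube<eT>& X, Cube<eT>& Y, Mat<eT>& colbuf) const {
    const uword B = X.n_slices;
    Y.set_size(uword(Ho) * Wo, cout, B);
    for (uword s = 0; s < B; ++s) {
      im2col(X.slice(s), colbuf);
      Y.slice(s) = colbuf * Wm.val;
      for (int o = 0; o < cout; ++o) {
        Y.slice(s).col(o) += b.val(o, 0);
      }
    }
  }

  // accumulates into Wm.g / b.g; writes dX unless skip_dx
  void backward(const Cube<eT>& X, const Cube<eT>& dY, Cube<eT>& dX,
                bool skip_dx, Mat<eT>& colbuf, Mat<eT>& dcolbuf) {
    const uword B = X.n_slices;
    Wm.g.zeros(); b.g.zeros();
    if (!skip_dx) dX.zeros(uword(H) * W, cin, B);
    for (uword s = 0; s < B; ++s) {
      im2col(X.slice(s), colbuf);
      Wm.g += colbuf.t() * dY.slice(s);
      b.g += sum(dY.slice(s), 0).t();
      if (!skip_dx) {
        dcolbuf = dY.slice(s) * Wm.val.t();
        col2im_add(dcolbuf, dX.slice(s));
      }
    }
  }
};

// ------------------------------------------------------------------ batchnorm

template <typename eT>
struct BNLayer {
  int C;
  uword Npix;  // H*W of the feature map
  Param<eT> gamma, beta;
  Col<eT> rmean, rvar;          // running statistics (non-trainable)
  Col<eT> mu, istd;             // batch statistics cached for backward
  Col<eT> acc_mean, acc_var;    // accumulators for post-training re-estimation
  long n_accum = 0;
  // momentum 0.9 so running statistics converge within short training
  // schedules; eps matches the common framework default
  eT momentum = eT(0.9), eps = eT(1e-3);

  void configure(int C_, uword Npix_, const std::string& nm) {
    C = C_; Npix = Npix_;
    gamma.init(C, 1, nm + ".gamma"); gamma.val.ones();
    beta.init(C, 1, nm + ".beta");
    rmean.zeros(C); rvar.ones(C);
    mu.zeros(C); istd.ones(C);
    acc_mean.zeros(C); acc_var.zeros(C);
  }

  void start_accum() { acc_mean.zeros(); acc_var.zeros(); n_accum = 0; }
  void finish_accum() {
    if (n_accum > 0) { rmean = acc_mean / n_accum; rvar = acc_var / n_accum; }
  }

  void forward(const Cube<eT>& X, Cube<eT>& Y, bool training, bool update_stats,
               bool accumulate = false) {
    const uword B = X.n_slices, N = Npix * B;
    if (accumulate && n_accum >= 0) ++n_accum;
    Y.set_size(size(X));
    for (int c = 0; c < C; ++c) {
      eT m, is;
      if (training) {
        eT s = 0, ss = 0;
        for (uword b = 0; b < B; ++b) {
          const eT* x = X.slice(b).colptr(c);
          for (uword i = 0; i < Npix; ++i) { s += x[i]; ss += x[i] * x[i]; }
        }
        m = s / N;
        eT var = ss / N - m * m;
        if (var < eT(0)) var = eT(0);
        is = eT(1) / std::sqrt(var + eps);
        mu(c) = m; istd(c) = is;
        if (update_stats) {
          rmean(c) = momentum * rmean(c) + (eT(1) - momentum) * m;
          rvar(c) = momentum * rvar(c) + (eT(1) - momentum) * var;
        }
        if (accumulate) { acc_mean(c) += m; acc_var(c) += var; }
      } else {
        m = rmean(c);
        is = eT(1) / std::sqrt(rvar(c) + eps);
      }
      const eT g = gamma.val(c), bta = beta.val(c);
      for (uword b = 0; b < B; ++b) {
        const eT* x = X.slice(b).colptr(c);
        eT* y = Y.slice(b).colptr(c);
        for (uword i = 0; i < Npix; ++i) y[i] = g * (x[i] - m) * is + bta;
      }
    }
  }

  // apply with cached batch statistics (used to re-materialize the forward
  // output during backprop instead of storing it)
  void apply_cached(const Cube<eT>& X, Cube<eT>& Y) const {
    Y.set_size(size(X));
    for (int c = 0; c < C; ++c) {
      const eT g = gamma.val(c), bta = beta.val(c), m = mu(c), is = istd(c);
      for (uword b = 0; b < X.n_slices; ++b) {
        const eT* x = X.slice(b).colptr(c);
        eT* y = Y.slice(b).colptr(c);
        for (uword i = 0; i < Npix; ++i) y[i] = g * (x[i] - m) * is + bta;
      }
    }
  }

  // X is the layer input (re-materialized by the caller); overwrites dY in place
  // with dX and accumulates dgamma/dbeta.
  void backward(const Cube<eT>& X, Cube<eT>& dY) {
    const uword B = X.n_slices;
    const eT N = eT(Npix * B);
    gamma.g.zeros(); beta.g.zeros();
    for (int c = 0; c < C; ++c) {
      const eT m = mu(c), is = istd(c), g = gamma.val(c);
      eT sum_dy = 0, sum_dy_xhat = 0;
      for (uword b = 0; b < B; ++b) {
        const eT* x = X.slice(b).colptr(c);
        const eT* dy = dY.slice(b).colptr(c);
        for (uword i = 0; i < Npix; ++i) {
          sum_dy += dy[i];
          sum_dy_xhat += dy[i] * (x[i] - m) * is;
        }
      }
      gamma.g(c) = sum_dy_xhat;
      beta.g(c) = sum_dy;
      const eT k = g * is / N;
      for (uword b = 0; b < B; ++b) {
        const eT* x = X.slice(b).colptr(c);
        eT* dy = dY.slice(b).colptr(c);
        for (uword i = 0; i < Npix; ++i) {
          const eT xhat = (x[i] - m) * is;
          dy[i] = k * (N * dy[i] - sum_dy - xhat * sum_dy_xhat);
        }
      }
    }
  }
};

// -------------------------------------------------------------------- pooling

// valid 2x2 max-pool, stride 2; records the winning input pixel index
template <typename eT>
void maxpool_forward(const Cube<eT>& X, int H, int W,
                     Cube<eT>& Y, Cube<u32>& idx) {
  const int Ho = H / 2, Wo = W / 2;
  const uword B = X.n_slices, C = X.n_cols;
  Y.set_size(uword(Ho) * Wo, C, B);
  idx.set_size(uword(Ho) * Wo, C, B);
  for (uword b = 0; b < B; ++b) {
    for (uword c = 0; c < C; ++c) {
      const eT* x = X.slice(b).colptr(c);
      eT* y = Y.slice(b).colptr(c);
      u32* id = idx.slice(b).colptr(c);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = 2 * ho, w0 = 2 * wo;
          u32 best = u32(h0 + H * w0);
          eT bv = x[best];
          const int cand[3] = { h0 + 1 + H * w0, h0 + H * (w0 + 1),
                                h0 + 1 + H * (w0 + 1) };
          for (int t = 0; t < 3; ++t) {
            if (x[cand[t]] > bv) { bv = x[cand[t]]; best = u32(cand[t]); }
          }
          y[ho + uword(Ho) * wo] = bv;
          id[ho + uword(Ho) * wo] = best;
        }
      }
    }
  }
}

template <typename eT>
void maxpool_backward(const Cube<eT>& dY, const Cube<u32>& idx,
                      int H, int W, Cube<eT>& dX) {
  const uword B = dY.n_slices, C = dY.n_cols;
  dX.zeros(uword(H) * W, C, B);
  for (uword b = 0; b < B; ++b) {
    for (uword c = 0; c < C; ++c) {
      const eT* dy = dY.slice(b).colptr(c);
      const u32* id = idx.slice(b).colptr(c);
      eT* dx = dX.slice(b).colptr(c);
      for (uword i = 0; i < dY.n_rows; ++i) dx[id[i]] += dy[i];
    }
  }
}

// re-materialize a batch-norm layer's forward output from the cached
// pre-activation of the preceding convolution (saves storing it)
template <typename eT>
void bn_apply_from_z(BNLayer<eT>& bn, const Cube<eT>& z, Cube<eT>& out, bool gelu) {
  Cube<eT> a;
  act_apply(z, a, gelu);
  bn.apply_cached(a, out);
}

// --------------------------------------------------------------------- network

template <typename eT>
struct CDNet {
  int n_classes, side;
  // spatial sizes along the trace
  int H1, P1, H2, P2;  // conv-A out, pool-A out, block-2 spatial, pool-B out

  ConvLayer<eT> convA[4];  BNLayer<eT> bnA[4];
  ConvLayer<eT> convB3[2], convB1[2];  BNLayer<eT> bnB1[2], bnB2[2];
  ConvLayer<eT> convC3, convC1;  BNLayer<eT> bnC1, bnC2;
  Param<eT> Wd, bd;  // dense softmax head: Wd (n_classes x 256)

  long t_adam = 0;

  // caches for backprop (kept allocated across batches)
  Cube<eT> zA[4], poolA[4], cat1[2], zB3[2], zB1[2], poolB[2], catB,
           zC3, zC1;
  Cube<u32> idxA[4], idxB[2];
  Mat<eT> G, P;            // GAP output (256 x B), softmax probs
  Col<uword> ybatch;

  Mat<eT> colbuf, dcolbuf;  // shared im2col scratch

  CDNet(int n_classes_, int side_) : n_classes(n_classes_), side(side_) {
    H1 = (side + 1) / 2;  P1 = H1 / 2;  H2 = P1;  P2 = H2 / 2;
    if (P1 < 1 || P2 < 1)
      stop("input side %d is too small for the architecture", side_);
    for (int i = 0; i < 4; ++i) {
      std::string a = "a" + std::to_string(i + 1);
      convA[i].configure(3, 3, 2, 3, 64, side, side, a + "_conv");
      bnA[i].configure(64, uword(H1) * H1, a + "_bn");
    }
    for (int j = 0; j < 2; ++j) {
      std::string b = "b" + std::to_string(j + 1);
      convB3[j].configure(3, 3, 1, 128, 128, H2, H2, b + "_conv3");
      bnB1[j].configure(128, uword(H2) * H2, b + "_bn1");
      convB1[j].configure(1, 1, 1, 128, 128, H2, H2, b + "_conv1");
      bnB2[j].configure(128, uword(H2) * H2, b + "_bn2");
    }
    convC3.configure(3, 3, 1, 256, 256, P2, P2, "c_conv3");
    bnC1.configure(256, uword(P2) * P2, "c_bn1");
    convC1.configure(1, 1, 1, 256, 256, P2, P2, "c_conv1");
    bnC2.configure(256, uword(P2) * P2, "c_bn2");
    Wd.init(n_classes, 256, "head.W");
    bd.init(n_classes, 1, "head.b");
  }

  std::vector<Param<eT>*> params() {
    std::vector<Param<eT>*> out;
    for (int i = 0; i < 4; ++i) {
      out.push_back(&convA[i].Wm); out.push_back(&convA[i].b);
      out.push_back(&bnA[i].gamma); out.push_back(&bnA[i].beta);
    }
    for (int j = 0; j < 2; ++j) {
      out.push_back(&convB3[j].Wm); out.push_back(&convB3[j].b);
      out.push_back(&bnB1[j].gamma); out.push_back(&bnB1[j].beta);
      out.push_back(&convB1[j].Wm); out.push_back(&convB1[j].b);
      out.push_back(&bnB2[j].gamma); out.push_back(&bnB2[j].beta);
    }
    out.push_back(&convC3.Wm); out.push_back(&convC3.b);
    out.push_back(&bnC1.gamma); out.push_back(&bnC1.beta);
    out.push_back(&convC1.Wm); out.push_back(&convC1.b);
    out.push_back(&bnC2.gamma); out.push_back(&bnC2.beta);
    out.push_back(&Wd); out.push_back(&bd);
    return out;
  }

  std::vector<BNLayer<eT>*> bn_layers() {
    std::vector<BNLayer<eT>*> out;
    for (int i = 0; i < 4; ++i) out.push_back(&bnA[i]);
    for (int j = 0; j < 2; ++j) { out.push_back(&bnB1[j]); out.push_back(&bnB2[j]); }
    out.push_back(&bnC1); out.push_back(&bnC2);
    return out;
  }

  // forward pass; caches activations when training
  void forward(const Cube<eT>& X, bool training, bool update_stats,
               bool accumulate = false) {
    const uword B = X.n_slices;
    Cube<eT> a, bn, tmp;
    for (int i = 0; i < 4; ++i) {
      Cube<eT> z;
      convA[i].forward(X, z, colbuf);
      act_apply(z, a, false);
      bnA[i].forward(a, bn, training, update_stats, accumulate);
      Cube<u32> idx;
      maxpool_forward(bn, H1, H1, tmp, idx);
      if (training) { zA[i] = std::move(z); idxA[i] = std::move(idx); }
      poolA[i] = std::move(tmp);
    }
    for (int j = 0; j < 2; ++j) {
      cat1[j] = join_rows_channels(poolA[2 * j], poolA[2 * j + 1]);
      Cube<eT> z3;
      convB3[j].forward(cat1[j], z3, colbuf);
      act_apply(z3, a, false);
      bnB1[j].forward(a, bn, training, update_stats, accumulate);
      Cube<eT> z1;
      convB1[j].forward(bn, z1, colbuf);
      act_apply(z1, a, false);
      bnB2[j].forward(a, bn, training, update_stats, accumulate);
      Cube<u32> idx;
      maxpool_forward(bn, H2, H2, tmp, idx);
      if (training) {
        zB3[j] = std::move(z3); zB1[j] = std::move(z1); idxB[j] = std::move(idx);
      }
      poolB[j] = std::move(tmp);
    }
    catB = join_rows_channels(poolB[0], poolB[1]);
    {
      Cube<eT> z3;
      convC3.forward(catB, z3, colbuf);
      act_apply(z3, a, true);
      bnC1.forward(a, bn, training, update_stats, accumulate);
      Cube<eT> z1;
      convC1.forward(bn, z1, colbuf);
      act_apply(z1, a, true);
      bnC2.forward(a, bn, training, update_stats, accumulate);
      if (training) { zC3 = std::move(z3); zC1 = std::move(z1); }
      // global average pooling
      G.set_size(256, B);
      const eT inv = eT(1) / eT(bn.n_rows);
      for (uword b = 0; b < B; ++b) G.col(b) = sum(bn.slice(b), 0).t() * inv;
    }
    // softmax head
    P = Wd.val * G;
    P.each_col() += bd.val;
    for (uword b = 0; b < B; ++b) {
      P.col(b) -= P.col(b).max();
      P.col(b) = exp(P.col(b));
      P.col(b) /= accu(P.col(b));
    }
  }

  static Cube<eT> join_rows_channels(const Cube<eT>& A, const Cube<eT>& Bc) {
    Cube<eT> out(A.n_rows, A.n_cols + Bc.n_cols, A.n_slices);
    for (uword s = 0; s < A.n_slices; ++s) {
      out.slice(s).cols(0, A.n_cols - 1) = A.slice(s);
      out.slice(s).cols(A.n_cols, out.n_cols - 1) = Bc.slice(s);
    }
    return out;
  }

  double loss(const Col<uword>& y) const {
    double L = 0;
    for (uword b = 0; b < y.n_elem; ++b) {
      L -= std::log(std::max(double(P(y(b), b)), 1e-12));
    }
    return L / y.n_elem;
  }

  // full backward pass; fills every Param's gradient. X must be the same
  // input batch the preceding training-mode forward() saw.
  void backward(const Cube<eT>& X, const Col<uword>& y) {
    const uword B = y.n_elem;
    // softmax + cross-entropy
    Mat<eT> dZ = P;
    for (uword b = 0; b < B; ++b) dZ(y(b), b) -= eT(1);
    dZ /= eT(B);
    Wd.g = dZ * G.t();
    bd.g = sum(dZ, 1);
    Mat<eT> dG = Wd.val.t() * dZ;  // (256 x B)

    // GAP backward into bnC2 output
    const uword npix3 = uword(P2) * P2;
    Cube<eT> d(npix3, 256, B);
    const eT inv = eT(1) / eT(npix3);
    for (uword b = 0; b < B; ++b) {
      d.slice(b) = repmat(dG.col(b).t() * inv, npix3, 1);
    }
    Cube<eT> a, tmp;
    // block 3
    act_apply(zC1, a, true);        // bnC2 input
    bnC2.backward(a, d);
    act_backprop(zC1, d, true);     // d now holds dz for convC1
    bn_apply_from_z(bnC1, zC3, a, true);  // convC1 input = bnC1(gelu(zC3))
    convC1.backward(a, d, tmp, false, colbuf, dcolbuf);
    d = std::move(tmp);
    act_apply(zC3, a, true);        // bnC1 input
    bnC1.backward(a, d);
    act_backprop(zC3, d, true);
    convC3.backward(catB, d, tmp, false, colbuf, dcolbuf);
    d = std::move(tmp);             // gradient w.r.t. catB (P2*P2, 256, B)

    // split catB into the two ConvNetB branches
    for (int j = 0; j < 2; ++j) {
      Cube<eT> dp(uword(P2) * P2, 128, B);
      for (uword s = 0; s < B; ++s) {
        dp.slice(s) = d.slice(s).cols(j * 128, j * 128 + 127);
      }
      Cube<eT> db;
      maxpool_backward(dp, idxB[j], H2, H2, db);
      act_apply(zB1[j], a, false);  // bnB2 input
      bnB2[j].backward(a, db);
      act_backprop(zB1[j], db, false);
      bn_apply_from_z(bnB1[j], zB3[j], a, false);  // convB1 input
      convB1[j].backward(a, db, tmp, false, colbuf, dcolbuf);
      db = std::move(tmp);
      act_apply(zB3[j], a, false);  // bnB1 input
      bnB1[j].backward(a, db);
      act_backprop(zB3[j], db, false);
      convB3[j].backward(cat1[j], db, tmp, false, colbuf, dcolbuf);
      db = std::move(tmp);          // gradient w.r.t. cat1[j]

      // split into the two ConvNetA branches of this pair
      for (int h = 0; h < 2; ++h) {
        const int i = 2 * j + h;
        Cube<eT> dpa(uword(P1) * P1, 64, B);
        for (uword s = 0; s < B; ++s) {
          dpa.slice(s) = db.slice(s).cols(h * 64, h * 64 + 63);
        }
        Cube<eT> da;
        maxpool_backward(dpa, idxA[i], H1, H1, da);
        act_apply(zA[i], a, false);
        bnA[i].backward(a, da);
        act_backprop(zA[i], da, false);
        Cube<eT> unused;
        convA[i].backward(X, da, unused, true, colbuf, dcolbuf);
      }
    }
  }

  void adam_step(double lr, double beta1, double beta2, double eps) {
    ++t_adam;
    const eT b1 = eT(beta1), b2 = eT(beta2);
    const eT corr1 = eT(1) - std::pow(b1, eT(t_adam));
    const eT corr2 = eT(1) - std::pow(b2, eT(t_adam));
    for (Param<eT>* p : params()) {
      p->m = b1 * p->m + (eT(1) - b1) * p->g;
      p->v = b2 * p->v + (eT(1) - b2) * square(p->g);
      p->val -= eT(lr) * (p->m / corr1) / (sqrt(p->v / corr2) + eT(eps));
    }
  }

  void drop_caches() {
    catB.reset(); zC3.reset(); zC1.reset();
    for (int i = 0; i < 4; ++i) { zA[i].reset(); poolA[i].reset(); idxA[i].reset(); }
    for (int j = 0; j < 2; ++j) {
      cat1[j].reset(); zB3[j].reset(); zB1[j].reset(); poolB[j].reset();
      idxB[j].reset();
    }
  }
};

// --------------------------------------------------------------- handle & API

struct NetHandle {
  bool dbl;
  CDNet<float>* f = nullptr;
  CDNet<double>* d = nullptr;
  ~NetHandle() { delete f; delete d; }
};

static NetHandle* get_handle(SEXP ptr) {
  Rcpp::XPtr<NetHandle> xp(ptr);
  return xp.get();
}

// [[Rcpp::export]]
SEXP cdnet_create(int num_classes, int side, bool double_precision) {
  NetHandle* h = new NetHandle();
  h->dbl = double_precision;
  if (double_precision) h->d = new CDNet<double>(num_classes, side);
  else h->f = new CDNet<float>(num_classes, side);
  return Rcpp::XPtr<NetHandle>(h, true);
}

template <typename eT>
static void set_weights_impl(CDNet<eT>& net, List w) {
  CharacterVector nm = w.names();
  auto find = [&](const std::string& name) -> NumericVector {
    for (int i = 0; i < w.size(); ++i) {
      if (std::string(nm[i]) == name) return w[i];
    }
    stop("missing weight '%s'", name.c_str());
    return NumericVector();
  };
  // conv kernels arrive as (kh, kw, cin, cout) arrays
  auto set_conv = [&](ConvLayer<eT>& c) {
    NumericVector W = find(c.Wm.name);
    IntegerVector dims = W.attr("dim");
    if (dims.size() != 4 || dims[0] != c.kh || dims[1] != c.kw ||
        dims[2] != c.cin || dims[3] != c.cout) {
      stop("weight '%s' has the wrong shape", c.Wm.name.c_str());
    }
    for (int o = 0; o < c.cout; ++o)
      for (int ci = 0; ci < c.cin; ++ci)
        for (int kj = 0; kj < c.kw; ++kj)
          for (int ki = 0; ki < c.kh; ++ki) {
            const uword k = (uword(ci) * c.kh + ki) * c.kw + kj;
            c.Wm.val(k, o) =
              eT(W[ki + c.kh * (kj + c.kw * (ci + uword(c.cin) * o))]);
          }
    NumericVector b = find(c.b.name);
    for (int o = 0; o < c.cout; ++o) c.b.val(o, 0) = eT(b[o]);
  };
  auto set_bn = [&](BNLayer<eT>& bnl, const std::string& base) {
    NumericVector g = find(base + ".gamma"), bt = find(base + ".beta"),
                  rm = find(base + ".running_mean"), rv = find(base + ".running_var");
    for (int c = 0; c < bnl.C; ++c) {
      bnl.gamma.val(c, 0) = eT(g[c]); bnl.beta.val(c, 0) = eT(bt[c]);
      bnl.rmean(c) = eT(rm[c]); bnl.rvar(c) = eT(rv[c]);
    }
  };
  for (int i = 0; i < 4; ++i) {
    set_conv(net.convA[i]);
    set_bn(net.bnA[i], "a" + std::to_string(i + 1) + "_bn");
  }
  for (int j = 0; j < 2; ++j) {
    set_conv(net.convB3[j]); set_conv(net.convB1[j]);
    set_bn(net.bnB1[j], "b" + std::to_string(j + 1) + "_bn1");
    set_bn(net.bnB2[j], "b" + std::to_string(j + 1) + "_bn2");
  }
  set_conv(net.convC3); set_conv(net.convC1);
  set_bn(net.bnC1, "c_bn1"); set_bn(net.bnC2, "c_bn2");
  NumericVector Wdv = find("head.W");  // (256 x n_classes), R convention (in, out)
  IntegerVector wd_dims = Wdv.attr("dim");
  if (wd_dims.size() != 2 || wd_dims[0] != 256 || wd_dims[1] != net.n_classes)
    stop("head.W must be 256 x n_classes");
  for (int o = 0; o < net.n_classes; ++o)
    for (int c = 0; c < 256; ++c) net.Wd.val(o, c) = eT(Wdv[c + 256 * o]);
  NumericVector bd = find("head.b");
  for (int o = 0; o < net.n_classes; ++o) net.bd.val(o, 0) = eT(bd[o]);
}

// [[Rcpp::export]]
void cdnet_set_weights(SEXP ptr, List w) {
  NetHandle* h = get_handle(ptr);
  if (h->dbl) set_weights_impl(*h->d, w);
  else set_weights_impl(*h->f, w);
}

template <typename eT>
static List get_weights_impl(CDNet<eT>& net) {
  List out;
  auto get_conv = [&](ConvLayer<eT>& c) {
    NumericVector W(R_xlen_t(c.kh) * c.kw * c.cin * c.cout);
    W.attr("dim") = IntegerVector::create(c.kh, c.kw, c.cin, c.cout);
    for (int o = 0; o < c.cout; ++o)
      for (int ci = 0; ci < c.cin; ++ci)
        for (int kj = 0; kj < c.kw; ++kj)
          for (int ki = 0; ki < c.kh; ++ki) {
            const uword k = (uword(ci) * c.kh + ki) * c.kw + kj;
            W[ki + c.kh * (kj + c.kw * (ci + uword(c.cin) * o))] =
              double(c.Wm.val(k, o));
          }
    out[c.Wm.name] = W;
    NumericVector b(c.cout);
    for (int o = 0; o < c.cout; ++o) b[o] = double(c.b.val(o, 0));
    out[c.b.name] = b;
  };
  auto get_bn = [&](BNLayer<eT>& bnl, const std::string& base) {
    NumericVector g(bnl.C), bt(bnl.C), rm(bnl.C), rv(bnl.C);
    for (int c = 0; c < bnl.C; ++c) {
      g[c] = double(bnl.gamma.val(c, 0)); bt[c] = double(bnl.beta.val(c, 0));
      rm[c] = double(bnl.rmean(c)); rv[c] = double(bnl.rvar(c));
    }
    out[base + ".gamma"] = g; out[base + ".beta"] = bt;
    out[base + ".running_mean"] = rm; out[base + ".running_var"] = rv;
  };
  for (int i = 0; i < 4; ++i) {
    get_conv(net.convA[i]);
    get_bn(net.bnA[i], "a" + std::to_string(i + 1) + "_bn");
  }
  for (int j = 0; j < 2; ++j) {
    get_conv(net.convB3[j]); get_conv(net.convB1[j]);
    get_bn(net.bnB1[j], "b" + std::to_string(j + 1) + "_bn1");
    get_bn(net.bnB2[j], "b" + std::to_string(j + 1) + "_bn2");
  }
  get_conv(net.convC3); get_conv(net.convC1);
  get_bn(net.bnC1, "c_bn1"); get_bn(net.bnC2, "c_bn2");
  NumericMatrix Wd(256, net.n_classes);
  for (int o = 0; o < net.n_classes; ++o)
    for (int c = 0; c < 256; ++c) Wd(c, o) = double(net.Wd.val(o, c));
  out["head.W"] = Wd;
  NumericVector bd(net.n_classes);
  for (int o = 0; o < net.n_classes; ++o) bd[o] = double(net.bd.val(o, 0));
  out["head.b"] = bd;
  return out;
}

// [[Rcpp::export]]
List cdnet_get_weights(SEXP ptr) {
  NetHandle* h = get_handle(ptr);
  return h->dbl ? get_weights_impl(*h->d) : get_weights_impl(*h->f);
}

template <typename eT>
static Cube<eT> batch_to_cube(const NumericVector& x, int side, uword B) {
  Cube<eT> X(uword(side) * side, 3, B);
  const double* src = x.begin();
  eT* dst = X.memptr();
  const uword n = X.n_elem;
  for (uword i = 0; i < n; ++i) dst[i] = eT(src[i]);
  return X;
}

static uword check_batch(const NumericVector& x, int side) {
  IntegerVector dims = x.attr("dim");
  if (dims.size() != 4 || dims[0] != side || dims[1] != side || dims[2] != 3)
    stop("x must be a side x side x 3 x B array matching the network input");
  return uword(dims[3]);
}

template <typename eT>
static List train_batch_impl(CDNet<eT>& net, const NumericVector& x,
                             const IntegerVector& y, double lr, double beta1,
                             double beta2, double eps) {
  const uword B = check_batch(x, net.side);
  if (uword(y.size()) != B) stop("length(y) must equal the batch size");
  Cube<eT> X = batch_to_cube<eT>(x, net.side, B);
  Col<uword> yv(B);
  for (uword b = 0; b < B; ++b) {
    if (y[b] < 0 || y[b] >= net.n_classes) stop("label out of range");
    yv(b) = uword(y[b]);
  }
  net.forward(X, true, true);
  const double L = net.loss(yv);
  uword correct = 0;
  for (uword b = 0; b < B; ++b) {
    if (net.P.col(b).index_max() == yv(b)) ++correct;
  }
  net.backward(X, yv);
  net.adam_step(lr, beta1, beta2, eps);
  return List::create(Named("loss") = L,
                      Named("accuracy") = double(correct) / B);
}

// [[Rcpp::export]]
List cdnet_train_batch(SEXP ptr, NumericVector x, IntegerVector y,
                       double lr = 0.001, double beta1 = 0.9,
                       double beta2 = 0.999, double eps = 1e-7) {
  NetHandle* h = get_handle(ptr);
  return h->dbl ? train_batch_impl(*h->d, x, y, lr, beta1, beta2, eps)
                : train_batch_impl(*h->f, x, y, lr, beta1, beta2, eps);
}

template <typename eT>
static NumericMatrix predict_impl(CDNet<eT>& net, const NumericVector& x,
                                  int chunk) {
  const uword n = check_batch(x, net.side);
  NumericMatrix out(n, net.n_classes);
  const uword img = uword(net.side) * net.side * 3;
  for (uword at = 0; at < n; at += chunk) {
    const uword B = std::min<uword>(chunk, n - at);
    Cube<eT> X(uword(net.side) * net.side, 3, B);
    const double* src = x.begin() + at * img;
    eT* dst = X.memptr();
    for (uword i = 0; i < img * B; ++i) dst[i] = eT(src[i]);
    net.forward(X, false, false);
    for (uword b = 0; b < B; ++b)
      for (int c = 0; c < net.n_classes; ++c)
        out(at + b, c) = double(net.P(c, b));
  }
  net.drop_caches();
  return out;
}

// [[Rcpp::export]]
NumericMatrix cdnet_predict(SEXP ptr, NumericVector x, int chunk = 32) {
  NetHandle* h = get_handle(ptr);
  return h->dbl ? predict_impl(*h->d, x, chunk) : predict_impl(*h->f, x, chunk);
}

template <typename eT>
static List gradients_impl(CDNet<eT>& net, const NumericVector& x,
                           const IntegerVector& y) {
  const uword B = check_batch(x, net.side);
  Cube<eT> X = batch_to_cube<eT>(x, net.side, B);
  Col<uword> yv(B);
  for (uword b = 0; b < B; ++b) yv(b) = uword(y[b]);
  net.forward(X, true, false);  // training-mode BN, frozen running stats
  const double L = net.loss(yv);
  net.backward(X, yv);
  // export gradients in the same layout as the R-side weights:
  // conv kernels as (kh, kw, cin, cout), the head kernel as (256 x classes)
  List g;
  auto conv_grad = [&](ConvLayer<eT>& c) {
    NumericVector W(R_xlen_t(c.kh) * c.kw * c.cin * c.cout);
    W.attr("dim") = IntegerVector::create(c.kh, c.kw, c.cin, c.cout);
    for (int o = 0; o < c.cout; ++o)
      for (int ci = 0; ci < c.cin; ++ci)
        for (int kj = 0; kj < c.kw; ++kj)
          for (int ki = 0; ki < c.kh; ++ki)
            W[ki + c.kh * (kj + c.kw * (ci + uword(c.cin) * o))] =
              double(c.Wm.g((uword(ci) * c.kh + ki) * c.kw + kj, o));
    g[c.Wm.name] = W;
    NumericVector b(c.cout);
    for (int o = 0; o < c.cout; ++o) b[o] = double(c.b.g(o, 0));
    g[c.b.name] = b;
  };
  auto bn_grad = [&](BNLayer<eT>& bnl) {
    NumericVector gv(bnl.C), bv(bnl.C);
    for (int c = 0; c < bnl.C; ++c) {
      gv[c] = double(bnl.gamma.g(c, 0));
      bv[c] = double(bnl.beta.g(c, 0));
    }
    g[bnl.gamma.name] = gv;
    g[bnl.beta.name] = bv;
  };
  for (int i = 0; i < 4; ++i) { conv_grad(net.convA[i]); bn_grad(net.bnA[i]); }
  for (int j = 0; j < 2; ++j) {
    conv_grad(net.convB3[j]); bn_grad(net.bnB1[j]);
    conv_grad(net.convB1[j]); bn_grad(net.bnB2[j]);
  }
  conv_grad(net.convC3); bn_grad(net.bnC1);
  conv_grad(net.convC1); bn_grad(net.bnC2);
  NumericMatrix Wd(256, net.n_classes);
  for (int o = 0; o < net.n_classes; ++o)
    for (int c = 0; c < 256; ++c) Wd(c, o) = double(net.Wd.g(o, c));
  g["head.W"] = Wd;
  NumericVector bd(net.n_classes);
  for (int o = 0; o < net.n_classes; ++o) bd[o] = double(net.bd.g(o, 0));
  g["head.b"] = bd;
  net.drop_caches();
  return List::create(Named("loss") = L, Named("gradients") = g);
}

// [[Rcpp::export]]
List cdnet_gradients(SEXP ptr, NumericVector x, IntegerVector y) {
  NetHandle* h = get_handle(ptr);
  return h->dbl ? gradients_impl(*h->d, x, y) : gradients_impl(*h->f, x, y);
}

template <typename eT>
static double loss_impl(CDNet<eT>& net, const NumericVector& x,
                        const IntegerVector& y) {
  const uword B = check_batch(x, net.side);
  Cube<eT> X = batch_to_cube<eT>(x, net.side, B);
  Col<uword> yv(B);
  for (uword b = 0; b < B; ++b) yv(b) = uword(y[b]);
  net.forward(X, true, false);
  const double L = net.loss(yv);
  net.drop_caches();
  return L;
}

// [[Rcpp::export]]
double cdnet_loss(SEXP ptr, NumericVector x, IntegerVector y) {
  NetHandle* h = get_handle(ptr);
  return h->dbl ? loss_impl(*h->d, x, y) : loss_impl(*h->f, x, y);
}

template <typename eT>
static List shapes_impl(CDNet<eT>& net) {
  List out;
  auto sh = [](int H, int W, int C) {
    return IntegerVector::create(H, W, C);
  };
  for (int i = 0; i < 4; ++i) {
    std::string a = "a" + std::to_string(i + 1);
    out[a + "_conv"] = sh(net.H1, net.H1, 64);
    out[a + "_pool"] = sh(net.P1, net.P1, 64);
  }
  out["concat_top"] = sh(net.P1, net.P1, 128);
  out["concat_bottom"] = sh(net.P1, net.P1, 128);
  for (int j = 0; j < 2; ++j) {
    std::string b = "b" + std::to_string(j + 1);
    out[b + "_conv3"] = sh(net.H2, net.H2, 128);
    out[b + "_conv1"] = sh(net.H2, net.H2, 128);
    out[b + "_pool"] = sh(net.P2, net.P2, 128);
  }
  out["concat_b"] = sh(net.P2, net.P2, 256);
  out["c_conv3"] = sh(net.P2, net.P2, 256);
  out["c_conv1"] = sh(net.P2, net.P2, 256);
  out["gap"] = sh(1, 1, 256);
  out["head"] = sh(1, 1, net.n_classes);
  return out;
}

// [[Rcpp::export]]
List cdnet_shapes(SEXP ptr) {
  NetHandle* h = get_handle(ptr);
  return h->dbl ? shapes_impl(*h->d) : shapes_impl(*h->f);
}

template <typename eT>
static List param_counts_impl(CDNet<eT>& net) {
  double trainable = 0;
  for (Param<eT>* p : net.params()) trainable += double(p->val.n_elem);
  double non_trainable = 0;
  for (BNLayer<eT>* b : net.bn_layers()) non_trainable += 2.0 * b->C;
  return List::create(Named("trainable") = trainable,
                      Named("non_trainable") = non_trainable);
}

// [[Rcpp::export]]
List cdnet_param_counts(SEXP ptr) {
  NetHandle* h = get_handle(ptr);
  return h->dbl ? param_counts_impl(*h->d) : param_counts_impl(*h->f);
}

template <typename eT>
static void refresh_stats_impl(CDNet<eT>& net, const NumericVector& x, int chunk) {
  const uword n = check_batch(x, net.side);
  const uword img = uword(net.side) * net.side * 3;
  for (BNLayer<eT>* b : net.bn_layers()) b->start_accum();
  for (uword at = 0; at < n; at += chunk) {
    const uword B = std::min<uword>(chunk, n - at);
    Cube<eT> X(uword(net.side) * net.side, 3, B);
    const double* src = x.begin() + at * img;
    eT* dst = X.memptr();
    for (uword i = 0; i < img * B; ++i) dst[i] = eT(src[i]);
    net.forward(X, true, false, true);
  }
  for (BNLayer<eT>* b : net.bn_layers()) b->finish_accum();
  net.drop_caches();
}

// Re-estimate every batch-norm layer's running statistics by averaging
// training-mode batch statistics over the given data with frozen weights.
// [[Rcpp::export]]
void cdnet_refresh_stats(SEXP ptr, NumericVector x, int chunk = 64) {
  NetHandle* h = get_handle(ptr);
  if (h->dbl) refresh_stats_impl(*h->d, x, chunk);
  else refresh_stats_impl(*h->f, x, chunk);
}

// --------------------------------------------------- standalone test primitives

// [[Rcpp::export]]
NumericVector nn_conv2d(NumericVector x, NumericVector w, NumericVector b,
                        int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  if (xd.size() != 3 || wd.size() != 4) stop("x must be 3-d, w 4-d");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  if (cin != C) stop("channel mismatch");
  ConvLayer<double> conv;
  conv.configure(kh, kw, stride, cin, cout, H, W, "t");
  for (int o = 0; o < cout; ++o)
    for (int ci = 0; ci < cin; ++ci)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          conv.Wm.val((uword(ci) * kh + ki) * kw + kj, o) =
            w[ki + kh * (kj + kw * (ci + uword(cin) * o))];
  for (int o = 0; o < cout; ++o) conv.b.val(o, 0) = b[o];
  Cube<double> X(uword(H) * W, C, 1);
  std::copy(x.begin(), x.end(), X.memptr());
  Cube<double> Y;
  Mat<double> buf;
  conv.forward(X, Y, buf);
  NumericVector out(Rcpp::Dimension(conv.Ho, conv.Wo, cout));
  std::copy(Y.memptr(), Y.memptr() + Y.n_elem, out.begin());
  return out;
}

// [[Rcpp::export]]
NumericVector nn_maxpool2(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 3) stop("x must be 3-d");
  const int H = xd[0], W = xd[1], C = xd[2];
  Cube<double> X(uword(H) * W, C, 1);
  std::copy(x.begin(), x.end(), X.memptr());
  Cube<double> Y;
  Cube<u32> idx;
  maxpool_forward(X, H, W, Y, idx);
  NumericVector out(Rcpp::Dimension(H / 2, W / 2, C));
  std::copy(Y.memptr(), Y.memptr() + Y.n_elem, out.begin());
  return out;
}

// [[Rcpp::export]]
NumericVector nn_selu(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = selu_one(double(x[i]));
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector nn_gelu(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = gelu_one(double(x[i]));
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
List nn_batchnorm_train(NumericVector x, NumericVector gamma,
                        NumericVector beta, double eps = 1e-3) {
  // x: (npix, C, B) cube serialized as an array
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 3) stop("x must be (npix, C, B)");
  const int npix = xd[0], C = xd[1], B = xd[2];
  BNLayer<double> bn;
  bn.configure(C, npix, "t");
  bn.eps = eps;
  for (int c = 0; c < C; ++c) {
    bn.gamma.val(c, 0) = gamma[c];
    bn.beta.val(c, 0) = beta[c];
  }
  Cube<double> X(npix, C, B);
  std::copy(x.begin(), x.end(), X.memptr());
  Cube<double> Y;
  bn.forward(X, Y, true, false);
  NumericVector out(Rcpp::Dimension(npix, C, B));
  std::copy(Y.memptr(), Y.memptr() + Y.n_elem, out.begin());
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    mu[c] = bn.mu(c);
    var[c] = 1.0 / (bn.istd(c) * bn.istd(c)) - eps;
  }
  return List::create(Named("y") = out, Named("mean") = mu,
                      Named("var") = var);
}
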