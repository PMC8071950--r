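// Two-head encoder-decoder for joint soma/vessel segmentation.
//
// A compact U-Net-style network: a contracting path of conv-conv-BN-pool
// levels (batch normalization immediately before each pooling), a two-conv
// bottleneck, and an expanding path where each stage applies dropout,
// nearest-neighbour 2x upsampling and a skip concatenation before two
// convolutions. Two sigmoid 1x1-conv heads emit one probability map per
// class. Training minimizes the Dice-logarithmic loss with per-instance,
// per-class sample weights, using Adam.
//
// Everything (init, shuffling, dropout) is driven by a std::mt19937 seeded
// from R, so a seed fully determines the run.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.9;

// ---------------------------------------------------------------------------
// primitives

// im2col for 3x3 same (zero) padding, transposed layout: (H*W) x (9*C).
// Each patch column is pixel-contiguous, so the copies run down cache
// lines in both source and destination.
static mat im2col3(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat out(H * W, 9 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* S = X.slice_memptr(c);
    int k = 0;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr, ++k) {
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        double* dst = out.colptr(c * 9 + k);
        for (int j = c0; j < c1; ++j) {
          const double* src = S + (std::size_t)(j + dc) * H + (r0 + dr);
          std::copy(src, src + (r1 - r0), dst + (std::size_t)j * H + r0);
        }
      }
    }
  }
  return out;
}

static cube col2im3(const mat& cols, int H, int W, int C) {
  cube dX(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* S = dX.slice_memptr(c);
    int k = 0;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr, ++k) {
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        const double* src_col = cols.colptr(c * 9 + k);
        for (int j = c0; j < c1; ++j) {
          double* dst = S + (std::size_t)(j + dc) * H + (r0 + dr);
          const double* src = src_col + (std::size_t)j * H + r0;
          for (int i = 0; i < r1 - r0; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return dX;
}

struct Conv {
  mat W;   // (C_out) x (9*C_in), or (C_out) x (C_in) for 1x1
  vec b;
  mat mW, vW;
  vec mb, vb;
  void init(int c_out, int fan_in_cols, std::mt19937& rng) {
    std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / fan_in_cols));
    W.set_size(c_out, fan_in_cols);
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = nd(rng);
    b.zeros(c_out);
    mW.zeros(c_out, fan_in_cols); vW.zeros(c_out, fan_in_cols);
    mb.zeros(c_out); vb.zeros(c_out);
  }
};

struct BN {
  vec gamma, beta, rmean, rvar;
  vec mg, vg, mb, vb;
  void init(int c) {
    gamma.ones(c); beta.zeros(c); rmean.zeros(c); rvar.ones(c);
    mg.zeros(c); vg.zeros(c); mb.zeros(c); vb.zeros(c);
  }
};

// conv forward: 3x3 same padding; cols_out gets the (H*W) x (9*Cin)
// im2col matrix for reuse in the backward pass.
static cube conv3_fwd(const Conv& L, const cube& X, mat& cols_out) {
  cols_out = im2col3(X);
  mat Y = cols_out * L.W.t();          // (H*W) x C_out
  Y.each_row() += L.b.t();
  cube out(X.n_rows, X.n_cols, L.W.n_rows);
  std::copy(Y.memptr(), Y.memptr() + Y.n_elem, out.memptr());
  return out;
}

// conv backward using the forward pass's cached im2col matrix;
// accumulates dW/db, returns dX.
static cube conv3_bwd(Conv& L, const mat& cols, const cube& dY,
                      mat& dW_acc, vec& db_acc) {
  const int H = dY.n_rows, W = dY.n_cols;
  const int Cin = cols.n_cols / 9;
  mat dYm((double*)dY.memptr(), H * W, dY.n_slices, false, true);  // view
  dW_acc += dYm.t() * cols;
  db_acc += arma::sum(dYm, 0).t();
  mat dcols = dYm * L.W;               // (H*W) x (9*Cin)
  return col2im3(dcols, H, W, Cin);
}

static cube relu(const cube& X) { return arma::clamp(X, 0.0, arma::datum::inf); }

static cube relu_bwd(const cube& Z, const cube& dA) {
  cube dZ = dA;
  dZ.elem(arma::find(Z <= 0)).zeros();
  return dZ;
}

// ---------------------------------------------------------------------------
// network definition

struct UNet {
  int D, F, K;           // depth, base filters, classes (= 2)
  double dropout;
  std::vector<Conv> e1, e2, d1, d2;
  std::vector<BN> bns;
  Conv b1, b2, head;

  int enc_ch(int d) const { return F << d; }
  int bot_ch() const { return F << D; }

  void init(int depth, int base, std::mt19937& rng) {
    D = depth; F = base; K = 2; dropout = 0.5;
    e1.resize(D); e2.resize(D); d1.resize(D); d2.resize(D); bns.resize(D);
    for (int d = 0; d < D; ++d) {
      int cin = (d == 0) ? 1 : enc_ch(d - 1);
      e1[d].init(enc_ch(d), 9 * cin, rng);
      e2[d].init(enc_ch(d), 9 * enc_ch(d), rng);
      bns[d].init(enc_ch(d));
    }
    b1.init(bot_ch(), 9 * enc_ch(D - 1), rng);
    b2.init(bot_ch(), 9 * bot_ch(), rng);
    for (int d = D - 1; d >= 0; --d) {
      int cin_up = (d == D - 1) ? bot_ch() : enc_ch(d + 1);
      d1[d].init(enc_ch(d), 9 * (cin_up + enc_ch(d)), rng);
      d2[d].init(enc_ch(d), 9 * enc_ch(d), rng);
    }
    head.init(K, enc_ch(0), rng);
  }
};

// caches for one forward pass over a batch
struct FwdCache {
  // [level][batch]
  std::vector<std::vector<cube>> e_z1, e_z2, e_xhat, e_skip;
  std::vector<std::vector<mat>> e_cols1, e_cols2, d_cols1, d_cols2;
  std::vector<std::vector<arma::ucube>> pool_arg;
  std::vector<vec> bn_mu, bn_s;
  std::vector<cube> bot_z1, bot_z2;
  std::vector<mat> bot_cols1, bot_cols2;
  std::vector<std::vector<cube>> d_dropmask, d_up_in, d_z1, d_z2;
  std::vector<std::vector<cube>> skip_grad;  // backward scratch
  std::vector<cube> head_in, probs;
};

static cube maxpool2(const cube& X, arma::ucube& argm) {
  const int Ho = X.n_rows / 2, Wo = X.n_cols / 2, C = X.n_slices;
  cube out(Ho, Wo, C);
  argm.set_size(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -arma::datum::inf;
        unsigned int bk = 0;
        for (int k = 0; k < 4; ++k) {
          const int r = 2 * i + (k & 1), cc = 2 * j + (k >> 1);
          const double v = X(r, cc, c);
          if (v > best) { best = v; bk = k; }
        }
        out(i, j, c) = best;
        argm(i, j, c) = bk;
      }
    }
  }
  return out;
}

static cube maxpool2_bwd(const cube& dY, const arma::ucube& argm, int H, int W) {
  cube dX(H, W, dY.n_slices, arma::fill::zeros);
  for (arma::uword c = 0; c < dY.n_slices; ++c) {
    for (arma::uword j = 0; j < dY.n_cols; ++j) {
      for (arma::uword i = 0; i < dY.n_rows; ++i) {
        const unsigned int k = argm(i, j, c);
        dX(2 * i + (k & 1), 2 * j + (k >> 1), c) += dY(i, j, c);
      }
    }
  }
  return dX;
}

static cube upsample2(const cube& X) {
  cube out(2 * X.n_rows, 2 * X.n_cols, X.n_slices);
  for (arma::uword c = 0; c < X.n_slices; ++c) {
    for (arma::uword j = 0; j < out.n_cols; ++j) {
      for (arma::uword i = 0; i < out.n_rows; ++i) {
        out(i, j, c) = X(i / 2, j / 2, c);
      }
    }
  }
  return out;
}

static cube upsample2_bwd(const cube& dY) {
  cube dX(dY.n_rows / 2, dY.n_cols / 2, dY.n_slices, arma::fill::zeros);
  for (arma::uword c = 0; c < dY.n_slices; ++c) {
    for (arma::uword j = 0; j < dY.n_cols; ++j) {
      for (arma::uword i = 0; i < dY.n_rows; ++i) {
        dX(i / 2, j / 2, c) += dY(i, j, c);
      }
    }
  }
  return dX;
}

// batch normalization over (batch, H, W) per channel, training mode.
static void bn_forward_train(BN& L, std::vector<cube>& Xs,
                             std::vector<cube>& xhat_out, vec& mu, vec& s) {
  const int B = Xs.size(), C = Xs[0].n_slices;
  const double N = (double)B * Xs[0].n_rows * Xs[0].n_cols;
  mu.zeros(C); vec var(C, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) mu(c) += arma::accu(Xs[b].slice(c));
  }
  mu /= N;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      var(c) += arma::accu(arma::square(Xs[b].slice(c) - mu(c)));
    }
  }
  var /= N;
  s = arma::sqrt(var + BN_EPS);
  L.rmean = BN_MOMENTUM * L.rmean + (1.0 - BN_MOMENTUM) * mu;
  L.rvar = BN_MOMENTUM * L.rvar + (1.0 - BN_MOMENTUM) * var;
  xhat_out.resize(B);
  for (int b = 0; b < B; ++b) {
    xhat_out[b] = Xs[b];
    for (int c = 0; c < C; ++c) {
      xhat_out[b].slice(c) = (Xs[b].slice(c) - mu(c)) / s(c);
      Xs[b].slice(c) = L.gamma(c) * xhat_out[b].slice(c) + L.beta(c);
    }
  }
}

static cube bn_forward_eval(const BN& L, const cube& X) {
  cube out = X;
  for (arma::uword c = 0; c < X.n_slices; ++c) {
    const double s = std::sqrt(L.rvar(c) + BN_EPS);
    out.slice(c) = L.gamma(c) * (X.slice(c) - L.rmean(c)) / s + L.beta(c);
  }
  return out;
}

// BN backward for the whole batch; returns dX per batch element.
static std::vector<cube> bn_backward(const BN& L,
                                     const std::vector<cube>& xhat,
                                     const vec& s,
                                     const std::vector<cube>& dY,
                                     vec& dgamma, vec& dbeta) {
  const int B = dY.size(), C = dY[0].n_slices;
  const double N = (double)B * dY[0].n_rows * dY[0].n_cols;
  vec sum_dy(C, arma::fill::zeros), sum_dy_xhat(C, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      sum_dy(c) += arma::accu(dY[b].slice(c));
      sum_dy_xhat(c) += arma::accu(dY[b].slice(c) % xhat[b].slice(c));
    }
  }
  dgamma += sum_dy_xhat;
  dbeta += sum_dy;
  std::vector<cube> dX(B);
  for (int b = 0; b < B; ++b) {
    dX[b] = dY[b];
    for (int c = 0; c < C; ++c) {
      dX[b].slice(c) = (L.gamma(c) / (N * s(c))) *
        (N * dY[b].slice(c) - sum_dy(c) - xhat[b].slice(c) * sum_dy_xhat(c));
    }
  }
  return dX;
}

// full forward over a batch. train = use batch BN stats + dropout.
static void forward_batch(UNet& net, const std::vector<mat>& imgs, bool train,
                          std::mt19937& rng, FwdCache& cc) {
  const int B = imgs.size(), D = net.D;
  cc.e_z1.assign(D, {}); cc.e_z2.assign(D, {});
  cc.e_cols1.assign(D, {}); cc.e_cols2.assign(D, {});
  cc.d_cols1.assign(D, {}); cc.d_cols2.assign(D, {});
  cc.e_xhat.assign(D, {}); cc.e_skip.assign(D, {}); cc.pool_arg.assign(D, {});
  cc.bn_mu.assign(D, vec()); cc.bn_s.assign(D, vec());
  cc.bot_cols1.resize(B); cc.bot_cols2.resize(B);
  cc.bot_z1.resize(B); cc.bot_z2.resize(B);
  cc.d_dropmask.assign(D, {}); cc.d_up_in.assign(D, {});
  cc.d_z1.assign(D, {}); cc.d_z2.assign(D, {});
  cc.head_in.resize(B); cc.probs.resize(B);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<cube> x(B);
  for (int b = 0; b < B; ++b) {
    x[b].set_size(imgs[b].n_rows, imgs[b].n_cols, 1);
    x[b].slice(0) = imgs[b];
  }
  // encoder
  for (int d = 0; d < D; ++d) {
    cc.e_z1[d].resize(B); cc.e_z2[d].resize(B);
    cc.e_cols1[d].resize(B); cc.e_cols2[d].resize(B);
    cc.e_skip[d].resize(B); cc.pool_arg[d].resize(B);
    std::vector<cube> post(B);
    for (int b = 0; b < B; ++b) {
      cc.e_z1[d][b] = conv3_fwd(net.e1[d], x[b], cc.e_cols1[d][b]);
      cube a1 = relu(cc.e_z1[d][b]);
      cc.e_z2[d][b] = conv3_fwd(net.e2[d], a1, cc.e_cols2[d][b]);
      post[b] = relu(cc.e_z2[d][b]);
    }
    if (train) {
      bn_forward_train(net.bns[d], post, cc.e_xhat[d], cc.bn_mu[d], cc.bn_s[d]);
    } else {
      for (int b = 0; b < B; ++b) post[b] = bn_forward_eval(net.bns[d], post[b]);
    }
    for (int b = 0; b < B; ++b) {
      cc.e_skip[d][b] = post[b];
      x[b] = maxpool2(post[b], cc.pool_arg[d][b]);
    }
  }
  // bottleneck
  for (int b = 0; b < B; ++b) {
    cc.bot_z1[b] = conv3_fwd(net.b1, x[b], cc.bot_cols1[b]);
    cube a1 = relu(cc.bot_z1[b]);
    cc.bot_z2[b] = conv3_fwd(net.b2, a1, cc.bot_cols2[b]);
    x[b] = relu(cc.bot_z2[b]);
  }
  // decoder
  for (int d = D - 1; d >= 0; --d) {
    cc.d_dropmask[d].resize(B); cc.d_up_in[d].resize(B);
    cc.d_cols1[d].resize(B); cc.d_cols2[d].resize(B);
    cc.d_z1[d].resize(B); cc.d_z2[d].resize(B);
    for (int b = 0; b < B; ++b) {
      if (train && net.dropout > 0) {
        cube mask(x[b].n_rows, x[b].n_cols, x[b].n_slices);
        for (arma::uword i = 0; i < mask.n_elem; ++i) {
          mask(i) = (unif(rng) < net.dropout) ? 0.0 : 1.0 / (1.0 - net.dropout);
        }
        cc.d_dropmask[d][b] = mask;
        x[b] %= mask;
      } else {
        cc.d_dropmask[d][b].reset();
      }
      cc.d_up_in[d][b] = x[b];
      cube up = upsample2(x[b]);
      cube cat = arma::join_slices(up, cc.e_skip[d][b]);
      cc.d_z1[d][b] = conv3_fwd(net.d1[d], cat, cc.d_cols1[d][b]);
      cube a1 = relu(cc.d_z1[d][b]);
      cc.d_z2[d][b] = conv3_fwd(net.d2[d], a1, cc.d_cols2[d][b]);
      x[b] = relu(cc.d_z2[d][b]);
    }
  }
  // heads: 1x1 conv + sigmoid
  for (int b = 0; b < B; ++b) {
    cc.head_in[b] = x[b];
    const int H = x[b].n_rows, W = x[b].n_cols, C = x[b].n_slices;
    mat Xm(C, H * W);
    for (int c = 0; c < C; ++c) Xm.row(c) = arma::vectorise(x[b].slice(c)).t();
    mat Z = net.head.W * Xm;
    Z.each_col() += net.head.b;
    cube pr(H, W, net.K);
    for (int k = 0; k < net.K; ++k) {
      pr.slice(k) = 1.0 / (1.0 + arma::exp(-arma::reshape(Z.row(k), H, W)));
    }
    cc.probs[b] = pr;
  }
}

// parameter gradients, zero-initialized to mirror the net's shapes
struct Grads {
  std::vector<mat> e1W, e2W, d1W, d2W;
  std::vector<vec> e1b, e2b, d1b, d2b, bng, bnb;
  mat b1W, b2W, headW;
  vec b1b, b2b, headb;
  void init(const UNet& n) {
    const int D = n.D;
    e1W.resize(D); e2W.resize(D); d1W.resize(D); d2W.resize(D);
    e1b.resize(D); e2b.resize(D); d1b.resize(D); d2b.resize(D);
    bng.resize(D); bnb.resize(D);
    for (int d = 0; d < D; ++d) {
      e1W[d].zeros(arma::size(n.e1[d].W)); e1b[d].zeros(n.e1[d].b.n_elem);
      e2W[d].zeros(arma::size(n.e2[d].W)); e2b[d].zeros(n.e2[d].b.n_elem);
      d1W[d].zeros(arma::size(n.d1[d].W)); d1b[d].zeros(n.d1[d].b.n_elem);
      d2W[d].zeros(arma::size(n.d2[d].W)); d2b[d].zeros(n.d2[d].b.n_elem);
      bng[d].zeros(n.bns[d].gamma.n_elem); bnb[d].zeros(n.bns[d].beta.n_elem);
    }
    b1W.zeros(arma::size(n.b1.W)); b1b.zeros(n.b1.b.n_elem);
    b2W.zeros(arma::size(n.b2.W)); b2b.zeros(n.b2.b.n_elem);
    headW.zeros(arma::size(n.head.W)); headb.zeros(n.head.b.n_elem);
  }
};

// backward pass for a batch given dL/d(probs).
static void backward_batch(UNet& net, FwdCache& cc,
                           const std::vector<cube>& dprobs, Grads& g) {
  const int B = dprobs.size(), D = net.D;
  cc.skip_grad.assign(D, {});
  std::vector<cube> dx(B);
  // heads
  for (int b = 0; b < B; ++b) {
    const cube& pr = cc.probs[b];
    const cube& hin = cc.head_in[b];
    const int H = hin.n_rows, W = hin.n_cols, C = hin.n_slices;
    mat dZ(net.K, H * W);
    for (int k = 0; k < net.K; ++k) {
      mat d = dprobs[b].slice(k) % pr.slice(k) % (1.0 - pr.slice(k));
      dZ.row(k) = arma::vectorise(d).t();
    }
    mat Xm(C, H * W);
    for (int c = 0; c < C; ++c) Xm.row(c) = arma::vectorise(hin.slice(c)).t();
    g.headW += dZ * Xm.t();
    g.headb += arma::sum(dZ, 1);
    mat dXm = net.head.W.t() * dZ;
    dx[b].set_size(H, W, C);
    for (int c = 0; c < C; ++c) dx[b].slice(c) = arma::reshape(dXm.row(c), H, W);
  }
  // decoder (reverse order: level 0 ran last)
  for (int d = 0; d < D; ++d) {
    std::vector<cube> dskip(B);
    for (int b = 0; b < B; ++b) {
      cube dz2 = relu_bwd(cc.d_z2[d][b], dx[b]);
      cube da1 = conv3_bwd(net.d2[d], cc.d_cols2[d][b], dz2, g.d2W[d], g.d2b[d]);
      cube dz1 = relu_bwd(cc.d_z1[d][b], da1);
      cube dcat = conv3_bwd(net.d1[d], cc.d_cols1[d][b], dz1, g.d1W[d], g.d1b[d]);
      const int c_up = cc.d_up_in[d][b].n_slices;
      cube dup = dcat.slices(0, c_up - 1);
      dskip[b] = dcat.slices(c_up, dcat.n_slices - 1);
      cube dpre = upsample2_bwd(dup);
      if (cc.d_dropmask[d][b].n_elem > 0) dpre %= cc.d_dropmask[d][b];
      dx[b] = dpre;
    }
    cc.skip_grad[d] = dskip;  // consumed by the encoder backward below
  }
  // bottleneck
  for (int b = 0; b < B; ++b) {
    cube dz2 = relu_bwd(cc.bot_z2[b], dx[b]);
    cube da1 = conv3_bwd(net.b2, cc.bot_cols2[b], dz2, g.b2W, g.b2b);
    cube dz1 = relu_bwd(cc.bot_z1[b], da1);
    dx[b] = conv3_bwd(net.b1, cc.bot_cols1[b], dz1, g.b1W, g.b1b);
  }
  // encoder (reverse: deepest level first)
  for (int d = D - 1; d >= 0; --d) {
    std::vector<cube> dpost(B);
    for (int b = 0; b < B; ++b) {
      const cube& skip = cc.e_skip[d][b];
      dpost[b] = maxpool2_bwd(dx[b], cc.pool_arg[d][b],
                              skip.n_rows, skip.n_cols);
      dpost[b] += cc.skip_grad[d][b];  // skip-connection gradient
    }
    std::vector<cube> dbn = bn_backward(net.bns[d], cc.e_xhat[d], cc.bn_s[d],
                                        dpost, g.bng[d], g.bnb[d]);
    for (int b = 0; b < B; ++b) {
      cube dz2 = relu_bwd(cc.e_z2[d][b], dbn[b]);
      cube da1 = conv3_bwd(net.e2[d], cc.e_cols2[d][b], dz2, g.e2W[d], g.e2b[d]);
      cube dz1 = relu_bwd(cc.e_z1[d][b], da1);
      dx[b] = conv3_bwd(net.e1[d], cc.e_cols1[d][b], dz1, g.e1W[d], g.e1b[d]);
    }
  }
}

// ---------------------------------------------------------------------------
// Dice-logarithmic loss (value + gradient w.r.t. the probability maps)

struct LossTerms {
  double total, soma_match, vessel_match, soma_cross, vessel_cross;
};

// matching soft dice: (2*sum(a%p)+eps)/(sum(a)+sum(p)+eps)
// cross soft dice:    (2*sum(a%p))   /(sum(a)+sum(p)+eps)
// each clamped into [tau, 1-tau] before the log; zero gradient when clamped.
static LossTerms dice_log_loss_grad(const mat& a_s, const mat& a_v,
                                    const cube& probs, double ws, double wv,
                                    double wx, double eps, double tau,
                                    cube* dprobs) {
  const mat& p_s = probs.slice(0);
  const mat& p_v = probs.slice(1);
  const double Sa_s = arma::accu(a_s), Sa_v = arma::accu(a_v);
  const double Sp_s = arma::accu(p_s), Sp_v = arma::accu(p_v);

  LossTerms lt;
  if (dprobs) dprobs->zeros(probs.n_rows, probs.n_cols, 2);

  // matching term for (a, p) on slice k with weight w
  auto match_term = [&](const mat& a, const mat& p, double Sa, double Sp,
                        double w, int k) -> double {
    const double num = 2.0 * arma::accu(a % p) + eps;
    const double den = Sa + Sp + eps;
    double dc = num / den;
    const bool clamped = (dc < tau) || (dc > 1.0 - tau);
    dc = std::min(std::max(dc, tau), 1.0 - tau);
    if (dprobs && !clamped) {
      dprobs->slice(k) += (-w / dc) * ((2.0 * a * den - num) / (den * den));
    }
    return -w * std::log(dc);
  };
  // cross term: p of one head against the other class's annotation
  auto cross_term = [&](const mat& a, const mat& p, double Sa, double Sp,
                        double w, int k) -> double {
    const double num = 2.0 * arma::accu(a % p);
    const double den = Sa + Sp + eps;
    double dc = num / den;
    const bool clamped = (dc < tau) || (dc > 1.0 - tau);
    dc = std::min(std::max(dc, tau), 1.0 - tau);
    if (dprobs && !clamped) {
      dprobs->slice(k) += (w / (1.0 - dc)) * ((2.0 * a * den - num) / (den * den));
    }
    return -w * std::log(1.0 - dc);
  };

  lt.soma_match = match_term(a_s, p_s, Sa_s, Sp_s, ws, 0);
  lt.vessel_match = match_term(a_v, p_v, Sa_v, Sp_v, wv, 1);
  lt.soma_cross = cross_term(a_s, p_v, Sa_s, Sp_v, wx, 1);
  lt.vessel_cross = cross_term(a_v, p_s, Sa_v, Sp_s, wx, 0);
  lt.total = lt.soma_match + lt.vessel_match + lt.soma_cross + lt.vessel_cross;
  return lt;
}

// ---------------------------------------------------------------------------
// Adam

struct Adam {
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void step_mat(mat& W, mat& m, mat& v, const mat& g) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    const double a = lr * std::sqrt(1 - std::pow(b2, t)) / (1 - std::pow(b1, t));
    W -= a * m / (arma::sqrt(v) + eps);
  }
  void step_vec(vec& W, vec& m, vec& v, const vec& g) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    const double a = lr * std::sqrt(1 - std::pow(b2, t)) / (1 - std::pow(b1, t));
    W -= a * m / (arma::sqrt(v) + eps);
  }
};

static void adam_update(UNet& n, Grads& g, Adam& opt) {
  ++opt.t;
  for (int d = 0; d < n.D; ++d) {
    opt.step_mat(n.e1[d].W, n.e1[d].mW, n.e1[d].vW, g.e1W[d]);
    opt.step_vec(n.e1[d].b, n.e1[d].mb, n.e1[d].vb, g.e1b[d]);
    opt.step_mat(n.e2[d].W, n.e2[d].mW, n.e2[d].vW, g.e2W[d]);
    opt.step_vec(n.e2[d].b, n.e2[d].mb, n.e2[d].vb, g.e2b[d]);
    opt.step_vec(n.bns[d].gamma, n.bns[d].mg, n.bns[d].vg, g.bng[d]);
    opt.step_vec(n.bns[d].beta, n.bns[d].mb, n.bns[d].vb, g.bnb[d]);
    opt.step_mat(n.d1[d].W, n.d1[d].mW, n.d1[d].vW, g.d1W[d]);
    opt.step_vec(n.d1[d].b, n.d1[d].mb, n.d1[d].vb, g.d1b[d]);
    opt.step_mat(n.d2[d].W, n.d2[d].mW, n.d2[d].vW, g.d2W[d]);
    opt.step_vec(n.d2[d].b, n.d2[d].mb, n.d2[d].vb, g.d2b[d]);
  }
  opt.step_mat(n.b1.W, n.b1.mW, n.b1.vW, g.b1W);
  opt.step_vec(n.b1.b, n.b1.mb, n.b1.vb, g.b1b);
  opt.step_mat(n.b2.W, n.b2.mW, n.b2.vW, g.b2W);
  opt.step_vec(n.b2.b, n.b2.mb, n.b2.vb, g.b2b);
  opt.step_mat(n.head.W, n.head.mW, n.head.vW, g.headW);
  opt.step_vec(n.head.b, n.head.mb, n.head.vb, g.headb);
}

// ---------------------------------------------------------------------------
// R <-> C++ parameter marshalling

static List params_to_list(const UNet& n) {
  List out;
  out["depth"] = n.D;
  out["base_filters"] = n.F;
  out["dropout"] = n.dropout;
  for (int d = 0; d < n.D; ++d) {
    std::string s = std::to_string(d + 1);
    out["e1_W_" + s] = wrap(n.e1[d].W); out["e1_b_" + s] = wrap(n.e1[d].b);
    out["e2_W_" + s] = wrap(n.e2[d].W); out["e2_b_" + s] = wrap(n.e2[d].b);
    out["bn_gamma_" + s] = wrap(n.bns[d].gamma);
    out["bn_beta_" + s] = wrap(n.bns[d].beta);
    out["bn_rmean_" + s] = wrap(n.bns[d].rmean);
    out["bn_rvar_" + s] = wrap(n.bns[d].rvar);
    out["d1_W_" + s] = wrap(n.d1[d].W); out["d1_b_" + s] = wrap(n.d1[d].b);
    out["d2_W_" + s] = wrap(n.d2[d].W); out["d2_b_" + s] = wrap(n.d2[d].b);
  }
  out["b1_W"] = wrap(n.b1.W); out["b1_b"] = wrap(n.b1.b);
  out["b2_W"] = wrap(n.b2.W); out["b2_b"] = wrap(n.b2.b);
  out["head_W"] = wrap(n.head.W); out["head_b"] = wrap(n.head.b);
  return out;
}

static void list_to_params(const List& li, UNet& n) {
  const int D = as<int>(li["depth"]);
  const int F = as<int>(li["base_filters"]);
  std::mt19937 rng(0);
  n.init(D, F, rng);  // shapes + Adam state; weights overwritten below
  n.dropout = as<double>(li["dropout"]);
  for (int d = 0; d < D; ++d) {
    std::string s = std::to_string(d + 1);
    n.e1[d].W = as<mat>(li["e1_W_" + s]); n.e1[d].b = as<vec>(li["e1_b_" + s]);
    n.e2[d].W = as<mat>(li["e2_W_" + s]); n.e2[d].b = as<vec>(li["e2_b_" + s]);
    n.bns[d].gamma = as<vec>(li["bn_gamma_" + s]);
    n.bns[d].beta = as<vec>(li["bn_beta_" + s]);
    n.bns[d].rmean = as<vec>(li["bn_rmean_" + s]);
    n.bns[d].rvar = as<vec>(li["bn_rvar_" + s]);
    n.d1[d].W = as<mat>(li["d1_W_" + s]); n.d1[d].b = as<vec>(li["d1_b_" + s]);
    n.d2[d].W = as<mat>(li["d2_W_" + s]); n.d2[d].b = as<vec>(li["d2_b_" + s]);
  }
  n.b1.W = as<mat>(li["b1_W"]); n.b1.b = as<vec>(li["b1_b"]);
  n.b2.W = as<mat>(li["b2_W"]); n.b2.b = as<vec>(li["b2_b"]);
  n.head.W = as<mat>(li["head_W"]); n.head.b = as<vec>(li["head_b"]);
}

static std::vector<mat> to_mats(const List& imgs) {
  std::vector<mat> out(imgs.size());
  for (int i = 0; i < imgs.size(); ++i) out[i] = as<mat>(imgs[i]);
  return out;
}

// ---------------------------------------------------------------------------
// exported entry points

// [[Rcpp::export]]
List cnn_init(int depth, int base_filters, double dropout, int seed) {
  std::mt19937 rng((unsigned int)seed);
  UNet net;
  net.init(depth, base_filters, rng);
  net.dropout = dropout;
  return params_to_list(net);
}

// [[Rcpp::export]]
List cnn_predict(List params, List imgs) {
  UNet net;
  list_to_params(params, net);
  std::vector<mat> X = to_mats(imgs);
  std::mt19937 rng(0);
  List out(X.size());
  for (std::size_t i = 0; i < X.size(); ++i) {
    FwdCache cc;
    std::vector<mat> one{X[i]};
    forward_batch(net, one, false, rng, cc);
    out[i] = List::create(_["soma"] = wrap(cc.probs[0].slice(0)),
                          _["vessel"] = wrap(cc.probs[0].slice(1)));
  }
  return out;
}

// inference-mode loss (running BN stats, no dropout) per instance.
// weights: m x 2 sample-weight matrix; terms are scaled by m * w_ij
// (cross terms by the mean of the two class factors).
// [[Rcpp::export]]
List cnn_eval_loss(List params, List imgs, List soma, List vessel,
                   arma::mat weights, double eps, double tau) {
  UNet net;
  list_to_params(params, net);
  std::vector<mat> X = to_mats(imgs);
  const int m = X.size();
  std::mt19937 rng(0);
  arma::mat terms(m, 4);
  vec totals(m);
  for (int i = 0; i < m; ++i) {
    FwdCache cc;
    std::vector<mat> one{X[i]};
    forward_batch(net, one, false, rng, cc);
    const double ws = m * weights(i, 0), wv = m * weights(i, 1);
    const double wx = 0.5 * (ws + wv);
    LossTerms lt = dice_log_loss_grad(as<mat>(soma[i]), as<mat>(vessel[i]),
                                      cc.probs[0], ws, wv, wx, eps, tau,
                                      nullptr);
    totals(i) = lt.total;
    terms(i, 0) = lt.soma_match; terms(i, 1) = lt.vessel_match;
    terms(i, 2) = lt.soma_cross; terms(i, 3) = lt.vessel_cross;
  }
  return List::create(_["total"] = wrap(totals), _["terms"] = wrap(terms));
}

// [[Rcpp::export]]
List cnn_train(List params, List imgs, List soma, List vessel,
               arma::mat weights, List val_imgs, List val_soma,
               List val_vessel, int epochs, double lr, int batch_size,
               int seed, double eps, double tau) {
  UNet net;
  list_to_params(params, net);
  std::vector<mat> X = to_mats(imgs);
  std::vector<mat> As(X.size()), Av(X.size());
  for (std::size_t i = 0; i < X.size(); ++i) {
    As[i] = as<mat>(soma[i]);
    Av[i] = as<mat>(vessel[i]);
  }
  std::vector<mat> VX = to_mats(val_imgs);
  std::vector<mat> VAs(VX.size()), VAv(VX.size());
  for (std::size_t i = 0; i < VX.size(); ++i) {
    VAs[i] = as<mat>(val_soma[i]);
    VAv[i] = as<mat>(val_vessel[i]);
  }
  const int m = X.size();
  std::mt19937 rng((unsigned int)seed);
  Adam opt; opt.lr = lr;
  vec train_hist(epochs), val_hist(epochs);
  List best_params;
  double best_val = arma::datum::inf;
  int best_epoch = 0;
  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    for (int start = 0; start < m; start += batch_size) {
      const int B = std::min(batch_size, m - start);
      std::vector<mat> bx(B);
      std::vector<int> idx(B);
      for (int b = 0; b < B; ++b) { idx[b] = order[start + b]; bx[b] = X[idx[b]]; }
      FwdCache cc;
      forward_batch(net, bx, true, rng, cc);
      std::vector<cube> dprobs(B);
      for (int b = 0; b < B; ++b) {
        const int i = idx[b];
        const double ws = m * weights(i, 0), wv = m * weights(i, 1);
        const double wx = 0.5 * (ws + wv);
        cube dp;
        LossTerms lt = dice_log_loss_grad(As[i], Av[i], cc.probs[b], ws, wv,
                                          wx, eps, tau, &dp);
        dprobs[b] = dp / (double)B;  // batch loss is the mean over instances
        ep_loss += lt.total;
      }
      Grads g;
      g.init(net);
      backward_batch(net, cc, dprobs, g);
      adam_update(net, g, opt);
    }
    train_hist(ep) = ep_loss / m;
    // validation: inference mode, uniform weights
    double vloss = 0.0;
    for (std::size_t i = 0; i < VX.size(); ++i) {
      FwdCache cc;
      std::vector<mat> one{VX[i]};
      forward_batch(net, one, false, rng, cc);
      LossTerms lt = dice_log_loss_grad(VAs[i], VAv[i], cc.probs[0],
                                        1.0, 1.0, 1.0, eps, tau, nullptr);
      vloss += lt.total;
    }
    vloss /= std::max((std::size_t)1, VX.size());
    val_hist(ep) = vloss;
    if (vloss < best_val) {  // strict: ties keep the earliest epoch
      best_val = vloss;
      best_epoch = ep + 1;
      best_params = params_to_list(net);
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["final_params"] = params_to_list(net),
                      _["best_params"] = best_params,
                      _["best_epoch"] = best_epoch,
                      _["train_loss"] = wrap(train_hist),
                      _["val_loss"] = wrap(val_hist));
}
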