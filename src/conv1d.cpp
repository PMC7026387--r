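#include <RcppArmadillo.h>

// The conda toolchain compiles packages with -O2 -march=nocona (SSE2 only).
// The hot kernels below carry explicit optimization pragmas plus runtime
// ISA dispatch (target_clones) so they vectorize with AVX2/FMA where the
// CPU supports it while remaining runnable anywhere.
#if defined(__GNUC__) && !defined(__clang__) && defined(__x86_64__)
#pragma GCC optimize("O3", "unroll-loops")
#define DEEPSOL_HOT __attribute__((target_clones("default", "arch=haswell")))
#else
#define DEEPSOL_HOT
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Activations are stored as (L*B x C) matrices: row index (b*L + l) holds
// position l of sample b, one column per channel, so every channel is
// contiguous within a sample and im2col reduces to long contiguous copies
// for stride-1 convolutions.
//
// Convolution weights are (k*Cin x Cout): row j*Cin + c is kernel offset j,
// input channel c.

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_forward(const arma::mat& X, const arma::mat& W,
                              const arma::vec& bias, const int Lin,
                              const int B, const int k, const int stride,
                              const int pad) {
  const int Cin = X.n_cols;
  const int Lout = (Lin + 2 * pad - k) / stride + 1;
  mat Xcol((uword)Lout * B, (uword)k * Cin, fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int off = j - pad;
    for (int c = 0; c < Cin; ++c) {
      const double* src = X.colptr(c);
      double* dst = Xcol.colptr((uword)j * Cin + c);
      for (int b = 0; b < B; ++b) {
        const double* sb = src + (uword)b * Lin;
        double* db = dst + (uword)b * Lout;
        if (stride == 1) {
          const int lo0 = std::max(0, -off);
          const int lo1 = std::min(Lout - 1, Lin - 1 - off);
          if (lo1 >= lo0)
            std::memcpy(db + lo0, sb + lo0 + off,
                        (size_t)(lo1 - lo0 + 1) * sizeof(double));
        } else {
          for (int lo = 0; lo < Lout; ++lo) {
            const int li = lo * stride + off;
            if (li >= 0 && li < Lin) db[lo] = sb[li];
          }
        }
      }
    }
  }
  mat Y = Xcol * W;
  Y.each_row() += bias.t();
  return Rcpp::List::create(Rcpp::Named("Y") = Y,
                            Rcpp::Named("Xcol") = Xcol);
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_backward(const arma::mat& Xcol, const arma::mat& W,
                               const arma::mat& dY, const int Lin,
                               const int B, const int k, const int stride,
                               const int pad, const int Cin,
                               const bool want_dx) {
  const int Lout = (Lin + 2 * pad - k) / stride + 1;
  mat dW = Xcol.t() * dY;
  vec db = sum(dY, 0).t();
  mat dX;
  if (want_dx) {
    mat dXcol = dY * W.t(); // (Lout*B x k*Cin)
    dX.zeros((uword)Lin * B, Cin);
    for (int j = 0; j < k; ++j) {
      const int off = j - pad;
      for (int c = 0; c < Cin; ++c) {
        const double* src = dXcol.colptr((uword)j * Cin + c);
        double* dst = dX.colptr(c);
        for (int b = 0; b < B; ++b) {
          const double* sb = src + (uword)b * Lout;
          double* db_ = dst + (uword)b * Lin;
          if (stride == 1) {
            const int lo0 = std::max(0, -off);
            const int lo1 = std::min(Lout - 1, Lin - 1 - off);
            for (int lo = lo0; lo <= lo1; ++lo) db_[lo + off] += sb[lo];
          } else {
            for (int lo = 0; lo < Lout; ++lo) {
              const int li = lo * stride + off;
              if (li >= 0 && li < Lin) db_[li] += sb[lo];
            }
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}

// act codes: 0 identity, 1 relu, 2 sigmoid, 3 softmax (across channels,
// i.e. across the columns of each row)
static void apply_act(mat& Y, const int act) {
  if (act == 1) {
    Y.transform([](double v) { return v > 0 ? v : 0.0; });
  } else if (act == 2) {
    Y.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
  } else if (act == 3) {
    const uword n = Y.n_rows, C = Y.n_cols;
    for (uword i = 0; i < n; ++i) {
      double mx = Y(i, 0);
      for (uword c = 1; c < C; ++c) mx = std::max(mx, Y(i, c));
      double s = 0;
      for (uword c = 0; c < C; ++c) { Y(i, c) = std::exp(Y(i, c) - mx); s += Y(i, c); }
      for (uword c = 0; c < C; ++c) Y(i, c) /= s;
    }
  }
}

// gradient through the activation given post-activation values Y
static mat act_grad(const mat& dA, const mat& Y, const int act) {
  if (act == 0) return dA;
  if (act == 1) return dA % (Y > 0);
  if (act == 2) return dA % Y % (1.0 - Y);
  // softmax across columns
  mat dZ(size(dA));
  const uword n = dA.n_rows, C = dA.n_cols;
  for (uword i = 0; i < n; ++i) {
    double s = 0;
    for (uword c = 0; c < C; ++c) s += dA(i, c) * Y(i, c);
    for (uword c = 0; c < C; ++c) dZ(i, c) = Y(i, c) * (dA(i, c) - s);
  }
  return dZ;
}

// [[Rcpp::export]]
Rcpp::List cpp_bn_act_forward(const arma::mat& X, const arma::vec& gamma,
                              const arma::vec& beta, const arma::vec& rmean,
                              const arma::vec& rvar, const bool training,
                              const double momentum, const double eps,
                              const int act) {
  const uword n = X.n_rows, C = X.n_cols;
  vec m(C), v(C);
  if (training) {
    for (uword c = 0; c < C; ++c) {
      const double* x = X.colptr(c);
      double s = 0, s2 = 0;
      for (uword i = 0; i < n; ++i) { s += x[i]; s2 += x[i] * x[i]; }
      m(c) = s / n;
      v(c) = std::max(0.0, s2 / n - m(c) * m(c));
    }
  } else {
    m = rmean;
    v = rvar;
  }
  vec istd = 1.0 / sqrt(v + eps);
  mat xhat(n, C), Y(n, C);
  for (uword c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    double* xh = xhat.colptr(c);
    double* y = Y.colptr(c);
    const double mc = m(c), ic = istd(c), g = gamma(c), b = beta(c);
    for (uword i = 0; i < n; ++i) {
      xh[i] = (x[i] - mc) * ic;
      y[i] = g * xh[i] + b;
    }
  }
  apply_act(Y, act);
  vec nm = rmean, nv = rvar;
  if (training) {
    nm = (1 - momentum) * rmean + momentum * m;
    nv = (1 - momentum) * rvar + momentum * v;
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("istd") = istd,
                            Rcpp::Named("mean") = nm, Rcpp::Named("var") = nv);
}

// [[Rcpp::export]]
Rcpp::List cpp_bn_act_backward(const arma::mat& dA, const arma::mat& Y,
                               const arma::mat& xhat, const arma::vec& istd,
                               const arma::vec& gamma, const int act) {
  mat dZ = act_grad(dA, Y, act);
  const uword n = dZ.n_rows, C = dZ.n_cols;
  vec dgamma(C), dbeta(C);
  mat dX(n, C);
  for (uword c = 0; c < C; ++c) {
    const double* dz = dZ.colptr(c);
    const double* xh = xhat.colptr(c);
    double s1 = 0, s2 = 0;
    for (uword i = 0; i < n; ++i) { s1 += dz[i]; s2 += dz[i] * xh[i]; }
    dbeta(c) = s1;
    dgamma(c) = s2;
    const double g = gamma(c), ic = istd(c);
    const double a = g * ic, b1 = s1 / n, b2 = s2 / n;
    double* dx = dX.colptr(c);
    for (uword i = 0; i < n; ++i) {
      dx[i] = a * (dz[i] - b1 - xh[i] * b2);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// [[Rcpp::export]]
Rcpp::List cpp_act_forward(const arma::mat& X, const int act) {
  mat Y = X;
  apply_act(Y, act);
  return Rcpp::List::create(Rcpp::Named("Y") = Y);
}

// [[Rcpp::export]]
arma::mat cpp_act_backward(const arma::mat& dA, const arma::mat& Y,
                           const int act) {
  return act_grad(dA, Y, act);
}

// ---------------------------------------------------------------------------
// Fused residual-network training step and prediction. The whole forward /
// loss / backward pass runs in C++ so only parameters, gradients and batch
// norm statistics cross the R boundary; internally activations are held
// channel-major (C x L*B) so every convolution window is one contiguous
// run of k*Cin doubles and the conv kernels need no im2col or BLAS call.
// The R-level resnet_forward / resnet_backward implement the identical
// computation and serve as the reference in the test suite.
//
// Flat parameter layout (R side packs/unpacks):
//   [0] stem_W  [1] stem_b
//   per block: bn1_g bn1_b conv1_W conv1_b bn2_g bn2_b conv2_W conv2_b
//              (+ proj_W proj_b when the block has a projection shortcut)
//   tail: bnf_g bnf_b fc_W fc_b
// Conv weights arrive as (k*Cin x Cout); they are transposed once per call.

struct CGeo {
  int Lin, Lout, Cin, Cout, k, stride, pad;
};

static CGeo cgeo(int Lin, int Cin, int Cout, int k, int stride, int pad) {
  CGeo g;
  g.Lin = Lin; g.Cin = Cin; g.Cout = Cout; g.k = k; g.stride = stride;
  g.pad = pad;
  g.Lout = (Lin + 2 * pad - k) / stride + 1;
  return g;
}

// Y (Cout x Lout*B) = conv(X (Cin x Lin*B)); W is (k*Cin x Cout) so each
// output channel's weights are one contiguous column, and each window is
// one contiguous run of k*Cin doubles: every dot product is contiguous x
// contiguous. Four-way partial sums keep the reduction vectorizable with
// a fixed, deterministic association order.
static inline double dot4(const double* __restrict a,
                          const double* __restrict b, const int len) {
  double s0 = 0, s1 = 0, s2 = 0, s3 = 0;
  int t = 0;
  for (; t + 4 <= len; t += 4) {
    s0 += a[t] * b[t];
    s1 += a[t + 1] * b[t + 1];
    s2 += a[t + 2] * b[t + 2];
    s3 += a[t + 3] * b[t + 3];
  }
  double s = (s0 + s1) + (s2 + s3);
  for (; t < len; ++t) s += a[t] * b[t];
  return s;
}

DEEPSOL_HOT
static void cm_conv_fwd(const mat& X, const mat& W, const vec& bias,
                        const CGeo& g, const int B, mat& Y) {
  Y.set_size(g.Cout, (uword)g.Lout * B);
  const int Cout = g.Cout, Cin = g.Cin, kC = g.k * Cin;
  const double* w = W.memptr();
  for (int b = 0; b < B; ++b) {
    const double* xb = X.colptr((uword)b * g.Lin);
    for (int lo = 0; lo < g.Lout; ++lo) {
      double* __restrict y = Y.colptr((uword)b * g.Lout + lo);
      const int start = lo * g.stride - g.pad;
      const int j0 = std::max(0, -start);
      const int j1 = std::min(g.k - 1, g.Lin - 1 - start);
      const double* xwin = xb + (ptrdiff_t)(start + j0) * Cin;
      const int t0 = j0 * Cin, len = (j1 + 1) * Cin - t0;
      for (int n = 0; n < Cout; ++n) {
        y[n] = bias(n) + dot4(xwin, w + (uword)n * kC + t0, len);
      }
    }
  }
}

DEEPSOL_HOT
static void cm_conv_bwd(const mat& X, const mat& W, const mat& dY,
                        const CGeo& g, const int B, mat& dW, vec& db,
                        mat& dX, const bool want_dx) {
  const int Cout = g.Cout, Cin = g.Cin, kC = g.k * Cin;
  dW.zeros(kC, Cout);
  db.zeros(Cout);
  if (want_dx) dX.zeros(Cin, (uword)g.Lin * B);
  const double* w = W.memptr();
  double* dw = dW.memptr();
  for (int b = 0; b < B; ++b) {
    const double* xb = X.colptr((uword)b * g.Lin);
    double* dxb = want_dx ? dX.colptr((uword)b * g.Lin) : nullptr;
    for (int lo = 0; lo < g.Lout; ++lo) {
      const double* __restrict dy = dY.colptr((uword)b * g.Lout + lo);
      const int start = lo * g.stride - g.pad;
      const int j0 = std::max(0, -start);
      const int j1 = std::min(g.k - 1, g.Lin - 1 - start);
      const double* xwin = xb + (ptrdiff_t)(start + j0) * Cin;
      double* dxwin = want_dx ? dxb + (ptrdiff_t)(start + j0) * Cin : nullptr;
      const int t0 = j0 * Cin, len = (j1 + 1) * Cin - t0;
      for (int n = 0; n < Cout; ++n) {
        const double dyn = dy[n];
        db(n) += dyn;
        double* __restrict dwcol = dw + (uword)n * kC + t0;
        for (int t = 0; t < len; ++t) dwcol[t] += dyn * xwin[t];
      }
      if (want_dx) {
        for (int n = 0; n < Cout; ++n) {
          const double dyn = dy[n];
          const double* __restrict wcol = w + (uword)n * kC + t0;
          for (int t = 0; t < len; ++t) dxwin[t] += dyn * wcol[t];
        }
      }
    }
  }
}

// act codes as above; in channel-major layout softmax runs down each column
DEEPSOL_HOT
static void cm_apply_act(mat& Y, const int act) {
  if (act == 1) {
    Y.transform([](double v) { return v > 0 ? v : 0.0; });
  } else if (act == 2) {
    Y.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
  } else if (act == 3) {
    const uword C = Y.n_rows, n = Y.n_cols;
    for (uword i = 0; i < n; ++i) {
      double* y = Y.colptr(i);
      double mx = y[0];
      for (uword c = 1; c < C; ++c) mx = std::max(mx, y[c]);
      double s = 0;
      for (uword c = 0; c < C; ++c) { y[c] = std::exp(y[c] - mx); s += y[c]; }
      for (uword c = 0; c < C; ++c) y[c] /= s;
    }
  }
}

DEEPSOL_HOT
static mat cm_act_grad(const mat& dA, const mat& Y, const int act) {
  if (act == 0) return dA;
  if (act == 1) return dA % (Y > 0);
  if (act == 2) return dA % Y % (1.0 - Y);
  mat dZ(size(dA));
  const uword C = dA.n_rows, n = dA.n_cols;
  for (uword i = 0; i < n; ++i) {
    const double* da = dA.colptr(i);
    const double* y = Y.colptr(i);
    double* dz = dZ.colptr(i);
    double s = 0;
    for (uword c = 0; c < C; ++c) s += da[c] * y[c];
    for (uword c = 0; c < C; ++c) dz[c] = y[c] * (da[c] - s);
  }
  return dZ;
}

struct CmBnCache {
  mat Y, xhat;
  vec istd;
};

DEEPSOL_HOT
static void cm_bn_act_fwd(const mat& X, const vec& gamma, const vec& beta,
                          vec& rmean, vec& rvar, const bool training,
                          const double momentum, const double eps,
                          const int act, CmBnCache& cc) {
  const uword C = X.n_rows, n = X.n_cols;
  vec m(C), v(C);
  if (training) {
    m.zeros(); v.zeros();
    for (uword i = 0; i < n; ++i) {
      const double* x = X.colptr(i);
      for (uword c = 0; c < C; ++c) { m(c) += x[c]; v(c) += x[c] * x[c]; }
    }
    m /= n;
    v = v / n - m % m;
    v.transform([](double z) { return z > 0 ? z : 0.0; });
    rmean = (1 - momentum) * rmean + momentum * m;
    rvar = (1 - momentum) * rvar + momentum * v;
  } else {
    m = rmean;
    v = rvar;
  }
  cc.istd = 1.0 / sqrt(v + eps);
  cc.xhat.set_size(C, n);
  cc.Y.set_size(C, n);
  for (uword i = 0; i < n; ++i) {
    const double* x = X.colptr(i);
    double* xh = cc.xhat.colptr(i);
    double* y = cc.Y.colptr(i);
    for (uword c = 0; c < C; ++c) {
      xh[c] = (x[c] - m(c)) * cc.istd(c);
      y[c] = gamma(c) * xh[c] + beta(c);
    }
  }
  cm_apply_act(cc.Y, act);
}

DEEPSOL_HOT
static void cm_bn_act_bwd(const mat& dA, const CmBnCache& cc, const vec& gamma,
                          const int act, mat& dX, vec& dgamma, vec& dbeta) {
  mat dZ = cm_act_grad(dA, cc.Y, act);
  const uword C = dZ.n_rows, n = dZ.n_cols;
  vec s1(C, fill::zeros), s2(C, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    const double* dz = dZ.colptr(i);
    const double* xh = cc.xhat.colptr(i);
    for (uword c = 0; c < C; ++c) { s1(c) += dz[c]; s2(c) += dz[c] * xh[c]; }
  }
  dbeta = s1;
  dgamma = s2;
  dX.set_size(C, n);
  vec a = gamma % cc.istd, b1 = s1 / n, b2 = s2 / n;
  for (uword i = 0; i < n; ++i) {
    const double* dz = dZ.colptr(i);
    const double* xh = cc.xhat.colptr(i);
    double* dx = dX.colptr(i);
    for (uword c = 0; c < C; ++c)
      dx[c] = a(c) * (dz[c] - b1(c) - xh[c] * b2(c));
  }
}

// geometry vector layout (ints):
// [0] input_length [1] stem_k [2] stem_cout [3] block_k [4] n_blocks
// [5] final_length [6] final_channels [7] head (0 flatten, 1 gap)
// [8] act code [9] use_bn
// block matrix (n_blocks x 6): l_in, c_in, c_out, stride, has_proj, l_mid

// [[Rcpp::export]]
Rcpp::List cpp_resnet_step(const arma::vec& xraw, const arma::vec& y,
                           const Rcpp::List& flat,
                           const Rcpp::List& flat_state,
                           const Rcpp::IntegerVector& gv,
                           const Rcpp::IntegerMatrix& bg,
                           const bool training, const int loss_kind,
                           const bool want_grads, const double momentum,
                           const double eps) {
  const int Lin = gv[0], stem_k = gv[1], stem_cout = gv[2], block_k = gv[3],
            nb = gv[4], Lf = gv[5], Cf = gv[6], head = gv[7], act = gv[8],
            use_bn = gv[9];
  const int B = xraw.n_elem / Lin;

  auto getm = [&](int i) { return Rcpp::as<mat>(flat[i]); };
  auto getv = [&](int i) { return Rcpp::as<vec>(flat[i]); };

  int pi = 0;
  mat stem_W = getm(pi++);
  vec stem_b = getv(pi++);
  struct BlockP {
    vec bn1_g, bn1_b, bn2_g, bn2_b;
    mat c1_W, c2_W, pj_W;
    vec c1_b, c2_b, pj_b;
    bool has_proj;
  };
  std::vector<BlockP> bp(nb);
  for (int i = 0; i < nb; ++i) {
    bp[i].bn1_g = getv(pi++); bp[i].bn1_b = getv(pi++);
    bp[i].c1_W = getm(pi++); bp[i].c1_b = getv(pi++);
    bp[i].bn2_g = getv(pi++); bp[i].bn2_b = getv(pi++);
    bp[i].c2_W = getm(pi++); bp[i].c2_b = getv(pi++);
    bp[i].has_proj = bg(i, 4) != 0;
    if (bp[i].has_proj) { bp[i].pj_W = getm(pi++); bp[i].pj_b = getv(pi++); }
  }
  vec bnf_g = getv(pi++), bnf_b = getv(pi++);
  mat fc_W = getm(pi++);
  vec fc_b = getv(pi++);

  int si = 0;
  std::vector<vec> st;
  for (int i = 0; i < (int)flat_state.size(); ++i)
    st.push_back(Rcpp::as<vec>(flat_state[i]));

  CGeo stem_geo = cgeo(Lin, 1, stem_cout, stem_k, 1, (stem_k - 1) / 2);
  std::vector<CGeo> g1(nb), g2(nb), gp(nb);
  for (int i = 0; i < nb; ++i) {
    g1[i] = cgeo(bg(i, 0), bg(i, 1), bg(i, 2), block_k, bg(i, 3),
                 (block_k - 1) / 2);
    g2[i] = cgeo(g1[i].Lout, bg(i, 2), bg(i, 2), block_k, 1,
                 (block_k - 1) / 2);
    if (bp[i].has_proj) gp[i] = cgeo(bg(i, 0), bg(i, 1), bg(i, 2), 1,
                                     bg(i, 3), 0);
  }

  // ---- forward ----
  mat X(const_cast<double*>(xraw.memptr()), 1, (uword)Lin * B, false, true);
  mat x;
  cm_conv_fwd(X, stem_W, stem_b, stem_geo, B, x);

  std::vector<CmBnCache> bc1(nb), bc2(nb);
  std::vector<mat> x_in(nb), a1(nb), a2(nb), h1(nb), h2(nb);
  for (int i = 0; i < nb; ++i) {
    x_in[i] = x;
    const mat* h;
    if (use_bn) {
      cm_bn_act_fwd(x, bp[i].bn1_g, bp[i].bn1_b, st[si + 0], st[si + 1],
                    training, momentum, eps, act, bc1[i]);
      h = &bc1[i].Y;
    } else {
      a1[i] = x;
      cm_apply_act(a1[i], act);
      h = &a1[i];
    }
    cm_conv_fwd(*h, bp[i].c1_W, bp[i].c1_b, g1[i], B, h1[i]);
    if (use_bn) {
      cm_bn_act_fwd(h1[i], bp[i].bn2_g, bp[i].bn2_b, st[si + 2], st[si + 3],
                    training, momentum, eps, act, bc2[i]);
      h = &bc2[i].Y;
    } else {
      a2[i] = h1[i];
      cm_apply_act(a2[i], act);
      h = &a2[i];
    }
    cm_conv_fwd(*h, bp[i].c2_W, bp[i].c2_b, g2[i], B, h2[i]);
    if (bp[i].has_proj) {
      mat sc;
      cm_conv_fwd(x, bp[i].pj_W, bp[i].pj_b, gp[i], B, sc);
      x = h2[i] + sc;
    } else {
      x = h2[i] + x;
    }
    if (use_bn) si += 4;
  }
  CmBnCache bcf;
  mat af;
  if (use_bn) {
    cm_bn_act_fwd(x, bnf_g, bnf_b, st[si + 0], st[si + 1], training, momentum,
                  eps, act, bcf);
    af = bcf.Y;
  } else {
    af = x;
    cm_apply_act(af, act);
  }
  // head: feature index l + Lf*c, sample columns
  mat H;
  if (head == 0) {
    H.set_size((uword)Lf * Cf, B);
    for (int b = 0; b < B; ++b) {
      double* hb = H.colptr(b);
      for (int l = 0; l < Lf; ++l) {
        const double* col = af.colptr((uword)b * Lf + l);
        for (int c = 0; c < Cf; ++c) hb[l + (uword)Lf * c] = col[c];
      }
    }
  } else {
    H.zeros(Cf, B);
    for (int b = 0; b < B; ++b) {
      double* hb = H.colptr(b);
      for (int l = 0; l < Lf; ++l) {
        const double* col = af.colptr((uword)b * Lf + l);
        for (int c = 0; c < Cf; ++c) hb[c] += col[c];
      }
      for (int c = 0; c < Cf; ++c) hb[c] /= Lf;
    }
  }
  vec pred = H.t() * fc_W.col(0) + fc_b(0);

  Rcpp::List state_out(flat_state.size());
  for (int i = 0; i < (int)st.size(); ++i) state_out[i] = st[i];

  if (!want_grads) {
    return Rcpp::List::create(Rcpp::Named("pred") = pred,
                              Rcpp::Named("state") = state_out);
  }

  // ---- loss ----
  vec r = pred - y;
  double sse = dot(r, r);
  double loss;
  vec dpred;
  if (loss_kind == 1) {
    loss = sse / B;
    dpred = 2.0 * r / B;
  } else {
    const double ybar = mean(y);
    double sst = 0;
    for (int b = 0; b < B; ++b) sst += (y(b) - ybar) * (y(b) - ybar);
    if (sst <= std::numeric_limits<double>::epsilon() * B) {
      loss = sse / B;
      dpred = 2.0 * r / B;
    } else {
      loss = sse / sst - 1.0;
      dpred = 2.0 * r / sst;
    }
  }

  // ---- backward ----
  Rcpp::List grads(flat.size());
  mat dH = fc_W.col(0) * dpred.t();
  mat fc_dW = H * dpred;
  vec fc_db(1);
  fc_db(0) = accu(dpred);

  mat dx(af.n_rows, af.n_cols);
  if (head == 0) {
    for (int b = 0; b < B; ++b) {
      const double* hb = dH.colptr(b);
      for (int l = 0; l < Lf; ++l) {
        double* col = dx.colptr((uword)b * Lf + l);
        for (int c = 0; c < Cf; ++c) col[c] = hb[l + (uword)Lf * c];
      }
    }
  } else {
    for (int b = 0; b < B; ++b) {
      const double* hb = dH.colptr(b);
      for (int l = 0; l < Lf; ++l) {
        double* col = dx.colptr((uword)b * Lf + l);
        for (int c = 0; c < Cf; ++c) col[c] = hb[c] / Lf;
      }
    }
  }
  vec bnf_dg, bnf_db_;
  if (use_bn) {
    mat tmp;
    cm_bn_act_bwd(dx, bcf, bnf_g, act, tmp, bnf_dg, bnf_db_);
    dx = tmp;
  } else {
    dx = cm_act_grad(dx, af, act);
  }

  struct BlockG {
    vec bn1_g, bn1_b, bn2_g, bn2_b;
    mat c1_W, c2_W, pj_W;
    vec c1_b, c2_b, pj_b;
  };
  std::vector<BlockG> bgo(nb);
  for (int i = nb - 1; i >= 0; --i) {
    BlockG& G = bgo[i];
    const mat& in2 = use_bn ? bc2[i].Y : a2[i];
    mat d2X;
    cm_conv_bwd(in2, bp[i].c2_W, dx, g2[i], B, G.c2_W, G.c2_b, d2X, true);
    mat dh;
    if (use_bn) {
      cm_bn_act_bwd(d2X, bc2[i], bp[i].bn2_g, act, dh, G.bn2_g, G.bn2_b);
    } else {
      dh = cm_act_grad(d2X, a2[i], act);
      G.bn2_g.set_size(0); G.bn2_b.set_size(0);
    }
    const mat& in1 = use_bn ? bc1[i].Y : a1[i];
    mat d1X;
    cm_conv_bwd(in1, bp[i].c1_W, dh, g1[i], B, G.c1_W, G.c1_b, d1X, true);
    if (use_bn) {
      mat tmp;
      cm_bn_act_bwd(d1X, bc1[i], bp[i].bn1_g, act, tmp, G.bn1_g, G.bn1_b);
      dh = tmp;
    } else {
      dh = cm_act_grad(d1X, a1[i], act);
      G.bn1_g.set_size(0); G.bn1_b.set_size(0);
    }
    mat dsc;
    if (bp[i].has_proj) {
      cm_conv_bwd(x_in[i], bp[i].pj_W, dx, gp[i], B, G.pj_W, G.pj_b, dsc,
                  true);
    } else {
      dsc = dx;
    }
    dx = dh + dsc;
  }
  mat stem_dW;
  vec stem_db;
  mat dummy;
  cm_conv_bwd(X, stem_W, dx, stem_geo, B, stem_dW, stem_db, dummy, false);

  int gi = 0;
  grads[gi++] = stem_dW;
  grads[gi++] = stem_db;
  for (int i = 0; i < nb; ++i) {
    grads[gi++] = bgo[i].bn1_g;
    grads[gi++] = bgo[i].bn1_b;
    grads[gi++] = bgo[i].c1_W;
    grads[gi++] = bgo[i].c1_b;
    grads[gi++] = bgo[i].bn2_g;
    grads[gi++] = bgo[i].bn2_b;
    grads[gi++] = bgo[i].c2_W;
    grads[gi++] = bgo[i].c2_b;
    if (bp[i].has_proj) {
      grads[gi++] = bgo[i].pj_W;
      grads[gi++] = bgo[i].pj_b;
    }
  }
  grads[gi++] = bnf_dg;
  grads[gi++] = bnf_db_;
  grads[gi++] = fc_dW;
  grads[gi++] = fc_db;

  return Rcpp::List::create(
      Rcpp::Named("pred") = pred, Rcpp::Named("loss") = loss,
      Rcpp::Named("grads") = grads, Rcpp::Named("state") = state_out);
}
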