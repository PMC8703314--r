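// Compact CNN engine for the 18-layer tumor/not-tumor classifier.
//
// Layout: a minibatch of N activation grids is stored as one
// (channels x N*(H+2)*(W+2)) single-precision matrix — every grid
// zero-padded by one pixel, pixels in column-major order within each
// sample block (p = i + j*(H+2)).  A 3x3 stride-1 SAME convolution then
// decomposes into nine shifted GEMMs
//   Z[:, span] += W_k * A[:, span + offset_k]
// over one contiguous span covering the whole batch, with no im2col
// patch matrix; the pad rings are re-zeroed after the accumulation
// (shifts never reach past a neighbouring sample's pad ring, so samples
// cannot mix).  Pooling is 2x2 stride 2; the dense tail is batched as
// plain matrix products.  The layer stack is fixed (conv-relu, pool,
// conv-relu x2, pool, conv-relu x2, pool, flatten, fc-relu,
// fc-softmax); only the filter counts vary (the published stack scaled
// by an integer divisor).  Arithmetic is float32 — the customary
// precision for CNN training — and strictly sequential, so results are
// bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
typedef arma::fmat fmat;
typedef arma::fvec fvec;

// geometry of a batch of padded grids
struct Grid {
  int H, W, N;
  int Hp() const { return H + 2; }
  int Np() const { return (H + 2) * (W + 2); }   // pixels per sample
  int total() const { return N * Np(); }
  int s0() const { return 1 + Hp(); }            // first interior pixel
  int s1() const { return (N - 1) * Np() + H + W * Hp(); }  // last one
};

// zero every pad ring (and the inter-sample garbage) of a batch matrix
static void zero_rings(fmat& A, const Grid& g) {
  const int Hp = g.Hp(), Np = g.Np();
  for (int n = 0; n < g.N; ++n) {
    const int b = n * Np;
    A.cols(b, b + Hp - 1).zeros();
    A.cols(b + (g.W + 1) * Hp, b + Np - 1).zeros();
    for (int j = 1; j <= g.W; ++j) {
      A.col(b + j * Hp).zeros();
      A.col(b + j * Hp + g.H + 1).zeros();
    }
  }
}

// offsets of the 3x3 neighbourhood in padded pixel coordinates,
// matching the row blocks k = 0..8 of the (Cout x 9*Cin) weight matrix
// (dj outer, di inner, each in {-1,0,1})
static void offsets3(const Grid& g, int off[9]) {
  int k = 0;
  for (int dj = -1; dj <= 1; ++dj)
    for (int di = -1; di <= 1; ++di, ++k)
      off[k] = di + dj * g.Hp();
}

// single-precision GEMM, accumulating in place (C += alpha * op(A) op(B))
extern "C" void sgemm_(const char* transa, const char* transb,
                       const int* m, const int* n, const int* k,
                       const float* alpha, const float* a, const int* lda,
                       const float* b, const int* ldb, const float* beta,
                       float* c, const int* ldc);

static void sgemm_acc(char ta, char tb, int m, int n, int k,
                      const float* A, int lda, const float* B, int ldb,
                      float* C, int ldc, float beta = 1.0f) {
  const float alpha = 1.0f;
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

// in-place ReLU and ReLU-derivative masking (single pass, no temporaries)
static void relu_inplace(fmat& Z) {
  float* z = Z.memptr();
  const arma::uword n = Z.n_elem;
  for (arma::uword i = 0; i < n; ++i) if (z[i] < 0.0f) z[i] = 0.0f;
}
static void mask_by(fmat& dA, const fmat& A) {
  float* d = dA.memptr();
  const float* a = A.memptr();
  const arma::uword n = dA.n_elem;
  for (arma::uword i = 0; i < n; ++i) if (a[i] <= 0.0f) d[i] = 0.0f;
}

// Z = relu(conv3x3(A) + b) on the padded batch layout.  The nine
// shifted products accumulate straight into Z's contiguous column span
// via sgemm with beta = 1 — no patch matrix, no temporaries.
static fmat conv_relu(const fmat& A, const fmat& W, const fvec& b,
                      const Grid& g) {
  const int Cin = A.n_rows, Cout = W.n_rows;
  int off[9]; offsets3(g, off);
  fmat Z(Cout, g.total(), arma::fill::none);
  const int s0 = g.s0(), s1 = g.s1(), L = s1 - s0 + 1;
  if (Cin == 1) {
    // single-channel input: one GEMM on a 9-row patch matrix beats nine
    // memory-bound rank-1 accumulations
    fmat P(9, L);
    for (int k = 0; k < 9; ++k)
      P.row(k) = A.cols(s0 + off[k], s1 + off[k]);
    sgemm_acc('N', 'N', Cout, L, 9, W.memptr(), Cout,
              P.memptr(), 9, Z.colptr(s0), Cout, 0.0f);
  } else {
    for (int k = 0; k < 9; ++k) {
      sgemm_acc('N', 'N', Cout, L, Cin,
                W.colptr(k * Cin), Cout,
                A.colptr(s0 + off[k]), Cin,
                Z.colptr(s0), Cout, k == 0 ? 0.0f : 1.0f);
    }
  }
  Z.cols(0, s0 - 1).zeros();
  Z.cols(s1 + 1, g.total() - 1).zeros();
  // fused bias + ReLU over the span (ring columns fixed afterwards)
  const float* bp = b.memptr();
  for (int p = s0; p <= s1; ++p) {
    float* z = Z.colptr(p);
    for (int c = 0; c < Cout; ++c) {
      const float v = z[c] + bp[c];
      z[c] = v > 0.0f ? v : 0.0f;
    }
  }
  zero_rings(Z, g);
  return Z;
}

// backward through conv+ReLU: dZ already masked by the ReLU derivative
// and ring-zeroed.  Accumulates dW, db; optionally produces dA.
static void conv_back(const fmat& A, const fmat& W, const fmat& dZ,
                      const Grid& g, fmat& dW, fvec& db, fmat* dA) {
  const int Cin = A.n_rows, Cout = W.n_rows;
  int off[9]; offsets3(g, off);
  const int s0 = g.s0(), s1 = g.s1(), L = s1 - s0 + 1;
  if (Cin == 1) {
    fmat P(9, L);
    for (int k = 0; k < 9; ++k)
      P.row(k) = A.cols(s0 + off[k], s1 + off[k]);
    sgemm_acc('N', 'T', Cout, 9, L, dZ.colptr(s0), Cout,
              P.memptr(), 9, dW.memptr(), Cout);
  } else {
    for (int k = 0; k < 9; ++k) {
      // dW_k += dZ * A_shifted^T
      sgemm_acc('N', 'T', Cout, Cin, L,
                dZ.colptr(s0), Cout,
                A.colptr(s0 + off[k]), Cin,
                dW.colptr(k * Cin), Cout);
    }
  }
  db += arma::sum(dZ.cols(s0, s1), 1);
  if (dA) {
    // offset 0 (di = dj = -1) is written with beta = 0; every column it
    // does not cover is zeroed first so the remaining offsets can
    // accumulate with beta = 1
    dA->set_size(Cin, g.total());
    const int lo0 = s0 + off[0], hi0 = s1 + off[0];
    if (lo0 > 0) dA->cols(0, lo0 - 1).zeros();
    if (hi0 < g.total() - 1) dA->cols(hi0 + 1, g.total() - 1).zeros();
    for (int k = 0; k < 9; ++k) {
      sgemm_acc('T', 'N', Cin, L, Cout,
                W.colptr(k * Cin), Cout,
                dZ.colptr(s0), Cout,
                dA->colptr(s0 + off[k]), Cin, k == 0 ? 0.0f : 1.0f);
    }
    zero_rings(*dA, g);
  }
}

// 2x2 stride-2 max pooling, padded batch in -> padded batch out, with
// argmax bookkeeping (ties -> first in scan order: top-left,
// bottom-left, top-right, bottom-right)
static void maxpool2(const fmat& A, const Grid& gin,
                     fmat& O, arma::umat& idx, const Grid& gout) {
  const int C = A.n_rows;
  O.zeros(C, gout.total());
  idx.zeros(C, gout.total());
  const int Hp = gin.Hp(), Hq = gout.Hp();
  for (int n = 0; n < gin.N; ++n) {
    const int bi = n * gin.Np(), bo = n * gout.Np();
    for (int jo = 1; jo <= gout.W; ++jo) {
      for (int io = 1; io <= gout.H; ++io) {
        const int po = bo + io + jo * Hq;
        const arma::uword p00 = bi + (2 * io - 1) + (2 * jo - 1) * Hp;
        const float* a00 = A.colptr(p00);
        const float* a10 = A.colptr(p00 + 1);
        const float* a01 = A.colptr(p00 + Hp);
        const float* a11 = A.colptr(p00 + Hp + 1);
        float* o = O.colptr(po);
        arma::uword* ix = idx.colptr(po);
        for (int c = 0; c < C; ++c) {
          float v = a00[c]; arma::uword b = p00;
          if (a10[c] > v) { v = a10[c]; b = p00 + 1; }
          if (a01[c] > v) { v = a01[c]; b = p00 + Hp; }
          if (a11[c] > v) { v = a11[c]; b = p00 + Hp + 1; }
          o[c] = v; ix[c] = b;
        }
      }
    }
  }
}

// backward through max pooling fused with the upstream ReLU mask:
// the gradient goes to the argmax slot iff the pooled maximum B > 0
// (the window partition covers the interior exactly once, so all four
// slots are written and no zero-fill pass is needed)
static fmat maxpool2_back(const fmat& dO, const arma::umat& idx,
                          const fmat& B, int C,
                          const Grid& gin, const Grid& gout) {
  fmat dA(C, gin.total(), arma::fill::none);
  const int Hp = gin.Hp(), Hq = gout.Hp();
  for (int n = 0; n < gin.N; ++n) {
    const int bi = n * gin.Np(), bo = n * gout.Np();
    for (int jo = 1; jo <= gout.W; ++jo)
      for (int io = 1; io <= gout.H; ++io) {
        const int po = bo + io + jo * Hq;
        const arma::uword p00 = bi + (2 * io - 1) + (2 * jo - 1) * Hp;
        float* a00 = dA.colptr(p00);
        float* a10 = dA.colptr(p00 + 1);
        float* a01 = dA.colptr(p00 + Hp);
        float* a11 = dA.colptr(p00 + Hp + 1);
        const float* d = dO.colptr(po);
        const float* bmax = B.colptr(po);
        const arma::uword* ix = idx.colptr(po);
        for (int c = 0; c < C; ++c) {
          a00[c] = 0.0f; a10[c] = 0.0f; a01[c] = 0.0f; a11[c] = 0.0f;
          if (bmax[c] > 0.0f) dA(c, ix[c]) = d[c];
        }
      }
  }
  zero_rings(dA, gin);
  return dA;
}

struct Params {
  fmat W[7];
  fvec b[7];
};

static Params unpack(const List& params) {
  Params P;
  for (int l = 0; l < 7; ++l) {
    P.W[l] = arma::conv_to<fmat>::from(as<arma::mat>(params[2 * l]));
    P.b[l] = arma::conv_to<fvec>::from(as<arma::vec>(params[2 * l + 1]));
  }
  return P;
}

// copy the interiors of a padded batch into C x (H*W*N) unpadded
// column-major pixels, sample blocks in order
static fmat unpad(const fmat& A, const Grid& g) {
  fmat out(A.n_rows, g.H * g.W * g.N);
  const int Hp = g.Hp();
  for (int n = 0; n < g.N; ++n) {
    const int bi = n * g.Np(), bo = n * g.H * g.W;
    for (int j = 1; j <= g.W; ++j)
      out.cols(bo + (j - 1) * g.H, bo + j * g.H - 1) =
        A.cols(bi + j * Hp + 1, bi + j * Hp + g.H);
  }
  return out;
}

// scatter a C x (H*W*N) matrix back into the padded batch layout
static fmat pad_in(const fmat& U, const Grid& g) {
  fmat out(U.n_rows, g.total(), arma::fill::zeros);
  const int Hp = g.Hp();
  for (int n = 0; n < g.N; ++n) {
    const int bi = n * g.Np(), bo = n * g.H * g.W;
    for (int j = 1; j <= g.W; ++j)
      out.cols(bi + j * Hp + 1, bi + j * Hp + g.H) =
        U.cols(bo + (j - 1) * g.H, bo + j * g.H - 1);
  }
  return out;
}

struct Cache {
  Grid g0, g1, g2, g3;               // 128, 64, 32, 16 grids
  fmat A0, A1, A2, A3, A4, A5;       // padded post-ReLU activations
  fmat B1, B2, B3;                   // padded pooled activations
  arma::umat I1, I2, I3;             // pooling argmax (padded indices)
  fmat V, Z6, A6;                    // dense tail, one column per sample
  arma::mat P2;                      // class probabilities (N x 2, double)
};

static void forward_pass(const arma::cube& xs, const Params& P, Cache& C) {
  const int H0 = xs.n_rows, W0 = xs.n_cols, N = xs.n_slices;
  C.g0 = Grid{H0, W0, N};
  C.g1 = Grid{H0 / 2, W0 / 2, N};
  C.g2 = Grid{H0 / 4, W0 / 4, N};
  C.g3 = Grid{H0 / 8, W0 / 8, N};

  fmat x0(1, H0 * W0 * N);
  for (int n = 0; n < N; ++n)
    x0.cols(n * H0 * W0, (n + 1) * H0 * W0 - 1) =
      arma::conv_to<fmat>::from(
        arma::reshape(xs.slice(n), 1, H0 * W0));
  C.A0 = pad_in(x0, C.g0);

  C.A1 = conv_relu(C.A0, P.W[0], P.b[0], C.g0);
  maxpool2(C.A1, C.g0, C.B1, C.I1, C.g1);
  C.A2 = conv_relu(C.B1, P.W[1], P.b[1], C.g1);
  C.A3 = conv_relu(C.A2, P.W[2], P.b[2], C.g1);
  maxpool2(C.A3, C.g1, C.B2, C.I2, C.g2);
  C.A4 = conv_relu(C.B2, P.W[3], P.b[3], C.g2);
  C.A5 = conv_relu(C.A4, P.W[4], P.b[4], C.g2);
  maxpool2(C.A5, C.g2, C.B3, C.I3, C.g3);

  const int nflat = C.A5.n_rows * C.g3.H * C.g3.W;
  C.V = arma::reshape(unpad(C.B3, C.g3), nflat, N);
  C.Z6 = P.W[5] * C.V;
  C.Z6.each_col() += P.b[5];
  C.A6 = C.Z6;
  relu_inplace(C.A6);
  fmat Z7 = P.W[6] * C.A6;
  Z7.each_col() += P.b[6];

  C.P2.set_size(N, 2);
  for (int n = 0; n < N; ++n) {
    double a = Z7(0, n), b = Z7(1, n);
    const double m = std::max(a, b);
    const double ea = std::exp(a - m), eb = std::exp(b - m);
    C.P2(n, 0) = ea / (ea + eb);
    C.P2(n, 1) = eb / (ea + eb);
  }
}

// clipped averaged binary cross-entropy of a 2-vector softmax output
// against a one-hot target, predictions clipped to [eps, 1-eps]
static double bce2(double p0, double p1, int y, double eps = 1e-7) {
  double s = 0.0;
  const double p[2] = {p0, p1};
  for (int i = 0; i < 2; ++i) {
    const double yi = (i == y) ? 1.0 : 0.0;
    const double pi = std::min(std::max(p[i], eps), 1.0 - eps);
    s += yi * std::log(pi) + (1.0 - yi) * std::log(1.0 - pi);
  }
  return -s / 2.0;
}

static inline fmat relu_mask(const fmat& A) {
  return arma::conv_to<fmat>::from(A > 0);
}

// Forward pass on one slice.  Returns class probabilities and, if asked,
// the post-ReLU feature maps of the last convolution layer (the 32x32
// maps feeding the gradient-saliency stage) as an H x W x C cube.
// [[Rcpp::export]]
List cnn_forward_cpp(const arma::mat& x, const List& params,
                     bool want_features = false) {
  Params P = unpack(params);
  Cache C;
  arma::cube xs(x.n_rows, x.n_cols, 1);
  xs.slice(0) = x;
  forward_pass(xs, P, C);
  List out = List::create(
    Named("probs") = NumericVector::create(C.P2(0, 0), C.P2(0, 1)));
  if (want_features) {
    fmat F5 = unpad(C.A5, C.g2);             // nf x (side*side)
    const int side = C.g2.H, nf = F5.n_rows;
    arma::cube F(side, side, nf);
    for (int c = 0; c < nf; ++c)
      F.slice(c) = arma::conv_to<arma::mat>::from(
        arma::reshape(F5.row(c), side, side));
    out["features"] = F;
  }
  return out;
}

// Class probabilities for a stack of slices (H x W x N cube), processed
// in fixed-size sub-batches so memory stays flat
// [[Rcpp::export]]
arma::mat cnn_forward_batch_cpp(const arma::cube& xs, const List& params) {
  Params P = unpack(params);
  const int N = xs.n_slices, B = 25;
  arma::mat probs(N, 2);
  Cache C;
  for (int a = 0; a < N; a += B) {
    const int b = std::min(a + B, N);
    forward_pass(xs.subcube(0, 0, a, xs.n_rows - 1, xs.n_cols - 1, b - 1),
                 P, C);
    probs.rows(a, b - 1) = C.P2;
  }
  return probs;
}

// Summed parameter gradients and per-sample losses over a minibatch.
// y holds 0-based class indices; gradients come back in the parameter
// order W1,b1,...,W7,b7.
// [[Rcpp::export]]
List cnn_grad_batch_cpp(const arma::cube& xs, const List& params,
                        const arma::ivec& y) {
  Params P = unpack(params);
  const int N = xs.n_slices;
  fmat gW[7];
  fvec gb[7];
  for (int l = 0; l < 7; ++l) {
    gW[l] = arma::zeros<fmat>(P.W[l].n_rows, P.W[l].n_cols);
    gb[l] = arma::zeros<fvec>(P.b[l].n_elem);
  }

  Cache C;
  forward_pass(xs, P, C);
  arma::vec losses(N);
  for (int n = 0; n < N; ++n)
    losses(n) = bce2(C.P2(n, 0), C.P2(n, 1), y(n));

  // softmax + cross-entropy head: d(loss)/d(z7) = p - onehot(y)
  fmat dZ7 = arma::conv_to<fmat>::from(C.P2.t());
  for (int n = 0; n < N; ++n) dZ7(y(n), n) -= 1.0f;
  gW[6] += dZ7 * C.A6.t();
  gb[6] += arma::sum(dZ7, 1);
  fmat dZ6 = (P.W[6].t() * dZ7) % relu_mask(C.Z6);
  gW[5] += dZ6 * C.V.t();
  gb[5] += arma::sum(dZ6, 1);
  const int nflat = C.V.n_rows;
  fmat dB3 = pad_in(arma::reshape(P.W[5].t() * dZ6, C.A5.n_rows,
                                  (nflat / C.A5.n_rows) * N), C.g3);

  fmat dA5 = maxpool2_back(dB3, C.I3, C.B3, C.A5.n_rows, C.g2, C.g3);
  fmat dA4;
  conv_back(C.A4, P.W[4], dA5, C.g2, gW[4], gb[4], &dA4);
  mask_by(dA4, C.A4);
  fmat dB2;
  conv_back(C.B2, P.W[3], dA4, C.g2, gW[3], gb[3], &dB2);

  fmat dA3 = maxpool2_back(dB2, C.I2, C.B2, C.A3.n_rows, C.g1, C.g2);
  fmat dA2;
  conv_back(C.A2, P.W[2], dA3, C.g1, gW[2], gb[2], &dA2);
  mask_by(dA2, C.A2);
  fmat dB1;
  conv_back(C.B1, P.W[1], dA2, C.g1, gW[1], gb[1], &dB1);

  fmat dA1 = maxpool2_back(dB1, C.I1, C.B1, C.A1.n_rows, C.g0, C.g1);
  conv_back(C.A0, P.W[0], dA1, C.g0, gW[0], gb[0], nullptr);

  List grads(14);
  for (int l = 0; l < 7; ++l) {
    grads[2 * l] = wrap(arma::conv_to<arma::mat>::from(gW[l]));
    grads[2 * l + 1] = wrap(arma::conv_to<arma::vec>::from(gb[l]));
  }
  return List::create(Named("grads") = grads,
                      Named("losses") = NumericVector(losses.begin(),
                                                      losses.end()),
                      Named("probs") = C.P2);
}

// 8-connected component labelling of a binary mask (iterative flood fill)
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * H);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
            if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * H);
            }
          }
        }
      }
    }
  }
  return lab;
}
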