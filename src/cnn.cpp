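#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include "simrng.h"
#include <vector>

using namespace Rcpp;

// Compact CNN for (H, W, 3) cell crops:
//   rescale -> conv(16, 3x3, stride 1, relu) -> maxpool 2x2
//           -> conv(64, 3x3, stride 1, relu) -> maxpool 2x2
//           -> flatten -> dense(128, relu) -> dense(2, softmax)
// Trained with softmax cross-entropy and Adam. Forward/backward passes are
// im2col + GEMM in single precision, with the convolution GEMMs batched
// across the whole minibatch; pooling floors odd extents (the last
// row/column is dropped, as standard 2x2/stride-2 max pooling does).

typedef arma::fmat fmat;
typedef arma::fvec fvec;

struct Dims {
  int H, W, C;
  int OH1, OW1, PH1, PW1;
  int OH2, OW2, PH2, PW2;
  int F1, F2, D, DU;
  int NC1, NP1, NC2, NP2;  // columns per image at each stage
};

static Dims make_dims(int H, int W, int C, int F1, int F2, int DU) {
  Dims d;
  d.H = H; d.W = W; d.C = C; d.F1 = F1; d.F2 = F2; d.DU = DU;
  d.OH1 = H - 2; d.OW1 = W - 2;
  d.PH1 = d.OH1 / 2; d.PW1 = d.OW1 / 2;
  d.OH2 = d.PH1 - 2; d.OW2 = d.PW1 - 2;
  d.PH2 = d.OH2 / 2; d.PW2 = d.OW2 / 2;
  d.D = d.PH2 * d.PW2 * F2;
  d.NC1 = d.OH1 * d.OW1; d.NP1 = d.PH1 * d.PW1;
  d.NC2 = d.OH2 * d.OW2; d.NP2 = d.PH2 * d.PW2;
  return d;
}

// im2col for 3x3/stride-1 valid convolution into the column block starting
// at `col0`: column col0 + ox*OH + oy, row r = c*9 + kx*3 + ky.
static void im2col(const float* img, int H, int W, int C, fmat& X,
                   int col0) {
  const int OH = H - 2, OW = W - 2;
  for (int ox = 0; ox < OW; ++ox)
    for (int oy = 0; oy < OH; ++oy) {
      float* col = X.colptr(col0 + ox * OH + oy);
      for (int c = 0; c < C; ++c) {
        const float* pl = img + (size_t)H * W * c + (size_t)H * ox + oy;
        float* dst = col + c * 9;
        for (int kx = 0; kx < 3; ++kx) {
          const float* src = pl + (size_t)H * kx;
          dst[kx * 3] = src[0];
          dst[kx * 3 + 1] = src[1];
          dst[kx * 3 + 2] = src[2];
        }
      }
    }
}

// scatter-add transpose of im2col (gradient w.r.t. conv input)
static void col2im(const fmat& dX, int col0, int H, int W, int C,
                   float* dimg) {
  const int OH = H - 2, OW = W - 2;
  std::fill(dimg, dimg + (size_t)H * W * C, 0.0f);
  for (int ox = 0; ox < OW; ++ox)
    for (int oy = 0; oy < OH; ++oy) {
      const float* col = dX.colptr(col0 + ox * OH + oy);
      for (int c = 0; c < C; ++c) {
        float* pl = dimg + (size_t)H * W * c + (size_t)H * ox + oy;
        const float* src = col + c * 9;
        for (int kx = 0; kx < 3; ++kx) {
          float* dst = pl + (size_t)H * kx;
          dst[0] += src[kx * 3];
          dst[1] += src[kx * 3 + 1];
          dst[2] += src[kx * 3 + 2];
        }
      }
    }
}

// 2x2/stride-2 max pool of the column block [colA0, colA0 + OH*OW) of A
// into the block [colP0, colP0 + PH*PW) of P; idx records the absolute
// source column in A of each maximum.
static void maxpool(const fmat& A, int colA0, int OH, int OW, int PH,
                    int PW, fmat& P, int colP0, arma::umat& idx) {
  const int F = A.n_rows;
  for (int px = 0; px < PW; ++px)
    for (int py = 0; py < PH; ++py) {
      int j = px * PH + py;
      int c00 = colA0 + (2 * px) * OH + 2 * py;
      const int cols[4] = {c00, c00 + 1, c00 + OH, c00 + OH + 1};
      const float* a0 = A.colptr(cols[0]);
      const float* a1 = A.colptr(cols[1]);
      const float* a2 = A.colptr(cols[2]);
      const float* a3 = A.colptr(cols[3]);
      float* p = P.colptr(colP0 + j);
      arma::uword* ix = idx.colptr(colP0 + j);
      for (int f = 0; f < F; ++f) {
        float best = a0[f];
        int bi = cols[0];
        if (a1[f] > best) { best = a1[f]; bi = cols[1]; }
        if (a2[f] > best) { best = a2[f]; bi = cols[2]; }
        if (a3[f] > best) { best = a3[f]; bi = cols[3]; }
        p[f] = best;
        ix[f] = (arma::uword)bi;
      }
    }
}

struct Params {
  fmat W1, W2, W3, W4;
  fvec b1, b2, b3, b4;
};

static Params params_from_list(const List& w) {
  Params p;
  p.W1 = arma::conv_to<fmat>::from(as<arma::mat>(w["W1"]));
  p.b1 = arma::conv_to<fvec>::from(as<arma::vec>(w["b1"]));
  p.W2 = arma::conv_to<fmat>::from(as<arma::mat>(w["W2"]));
  p.b2 = arma::conv_to<fvec>::from(as<arma::vec>(w["b2"]));
  p.W3 = arma::conv_to<fmat>::from(as<arma::mat>(w["W3"]));
  p.b3 = arma::conv_to<fvec>::from(as<arma::vec>(w["b3"]));
  p.W4 = arma::conv_to<fmat>::from(as<arma::mat>(w["W4"]));
  p.b4 = arma::conv_to<fvec>::from(as<arma::vec>(w["b4"]));
  return p;
}

static List params_to_list(const Params& p) {
  return List::create(
    _["W1"] = arma::conv_to<arma::mat>::from(p.W1),
    _["b1"] = arma::conv_to<arma::vec>::from(p.b1),
    _["W2"] = arma::conv_to<arma::mat>::from(p.W2),
    _["b2"] = arma::conv_to<arma::vec>::from(p.b2),
    _["W3"] = arma::conv_to<arma::mat>::from(p.W3),
    _["b3"] = arma::conv_to<arma::vec>::from(p.b3),
    _["W4"] = arma::conv_to<arma::mat>::from(p.W4),
    _["b4"] = arma::conv_to<arma::vec>::from(p.b4));
}

// Glorot-uniform initialisation, deterministic for a given seed.
// [[Rcpp::export]]
List cpp_cnn_init(int H, int W, int C, int f1, int f2, int dense_units,
                  int n_classes, int seed) {
  Dims d = make_dims(H, W, C, f1, f2, dense_units);
  SimRng rg((uint64_t)(uint32_t)seed);
  auto glorot = [&](int rows, int cols, int fan_in, int fan_out) {
    double lim = std::sqrt(6.0 / (fan_in + fan_out));
    arma::mat M(rows, cols);
    for (arma::uword j = 0; j < M.n_cols; ++j)
      for (arma::uword i = 0; i < M.n_rows; ++i)
        M(i, j) = lim * (2.0 * rg.unif() - 1.0);
    return M;
  };
  return List::create(
    _["W1"] = glorot(f1, 9 * C, 9 * C, 9 * f1),
    _["b1"] = arma::vec(f1, arma::fill::zeros),
    _["W2"] = glorot(f2, 9 * f1, 9 * f1, 9 * f2),
    _["b2"] = arma::vec(f2, arma::fill::zeros),
    _["W3"] = glorot(dense_units, d.D, d.D, dense_units),
    _["b3"] = arma::vec(dense_units, arma::fill::zeros),
    _["W4"] = glorot(n_classes, dense_units, dense_units, n_classes),
    _["b4"] = arma::vec(n_classes, arma::fill::zeros));
}

// workspace for a batch of up to Bmax images
struct BatchWork {
  int Bmax = 0;
  std::vector<float> img, p1img, dp1img;
  fmat X1, A1, P1, X2, A2, F;
  arma::umat i1, i2;
  fmat dA1, dA2, dX2;
  void init(const Dims& d, int B, bool backward) {
    Bmax = B;
    img.resize((size_t)d.H * d.W * d.C);
    p1img.resize((size_t)d.NP1 * d.F1);
    X1.set_size(9 * d.C, (size_t)d.NC1 * B);
    A1.set_size(d.F1, (size_t)d.NC1 * B);
    P1.set_size(d.F1, (size_t)d.NP1 * B);
    i1.set_size(d.F1, (size_t)d.NP1 * B);
    X2.set_size(9 * d.F1, (size_t)d.NC2 * B);
    A2.set_size(d.F2, (size_t)d.NC2 * B);
    i2.set_size(d.F2, (size_t)d.NP2 * B);
    F.set_size(d.D, B);
    if (backward) {
      dp1img.resize(p1img.size());
      dA1.set_size(d.F1, (size_t)d.NC1 * B);
      dA2.set_size(d.F2, (size_t)d.NC2 * B);
      dX2.set_size(9 * d.F1, (size_t)d.NC2 * B);
    }
  }
};

static inline void relu_inplace(fmat& M, size_t ncols) {
  float* p = M.memptr();
  const size_t n = M.n_rows * ncols;
  for (size_t i = 0; i < n; ++i)
    if (p[i] < 0.0f) p[i] = 0.0f;
}

// forward the images X[, idx[start..start+B)] through the conv stack,
// leaving activations and pool indices in `wk` and features in wk.F
static void forward_conv(const double* xp, size_t imsz,
                         const std::vector<int>& idx, int start, int B,
                         const Dims& d, const Params& p, float rescale,
                         BatchWork& wk) {
  for (int b = 0; b < B; ++b) {
    const double* img = xp + imsz * idx[start + b];
    for (size_t i = 0; i < imsz; ++i) wk.img[i] = (float)img[i] * rescale;
    im2col(wk.img.data(), d.H, d.W, d.C, wk.X1, b * d.NC1);
  }
  wk.A1.head_cols((size_t)d.NC1 * B) =
    p.W1 * wk.X1.head_cols((size_t)d.NC1 * B);
  wk.A1.head_cols((size_t)d.NC1 * B).each_col() += p.b1;
  relu_inplace(wk.A1, (size_t)d.NC1 * B);
  for (int b = 0; b < B; ++b) {
    maxpool(wk.A1, b * d.NC1, d.OH1, d.OW1, d.PH1, d.PW1, wk.P1,
            b * d.NP1, wk.i1);
    for (int f = 0; f < d.F1; ++f) {
      float* dst = wk.p1img.data() + (size_t)d.NP1 * f;
      const int colP0 = b * d.NP1;
      for (int j = 0; j < d.NP1; ++j) dst[j] = wk.P1(f, colP0 + j);
    }
    im2col(wk.p1img.data(), d.PH1, d.PW1, d.F1, wk.X2, b * d.NC2);
  }
  wk.A2.head_cols((size_t)d.NC2 * B) =
    p.W2 * wk.X2.head_cols((size_t)d.NC2 * B);
  wk.A2.head_cols((size_t)d.NC2 * B).each_col() += p.b2;
  relu_inplace(wk.A2, (size_t)d.NC2 * B);
  for (int b = 0; b < B; ++b) {
    // pool2 writes straight into the flattened feature column
    float* fcol = wk.F.colptr(b);
    for (int px = 0; px < d.PW2; ++px)
      for (int py = 0; py < d.PH2; ++py) {
        int j = px * d.PH2 + py;
        int c00 = b * d.NC2 + (2 * px) * d.OH2 + 2 * py;
        const int cols[4] = {c00, c00 + 1, c00 + d.OH2, c00 + d.OH2 + 1};
        const float* a0 = wk.A2.colptr(cols[0]);
        const float* a1 = wk.A2.colptr(cols[1]);
        const float* a2 = wk.A2.colptr(cols[2]);
        const float* a3 = wk.A2.colptr(cols[3]);
        arma::uword* ix = wk.i2.colptr(b * d.NP2 + j);
        for (int f = 0; f < d.F2; ++f) {
          float best = a0[f];
          int bi = cols[0];
          if (a1[f] > best) { best = a1[f]; bi = cols[1]; }
          if (a2[f] > best) { best = a2[f]; bi = cols[2]; }
          if (a3[f] > best) { best = a3[f]; bi = cols[3]; }
          fcol[(size_t)d.NP2 * f + j] = best;
          ix[f] = (arma::uword)bi;
        }
      }
  }
}

static fmat softmax_cols(fmat Z) {
  for (arma::uword j = 0; j < Z.n_cols; ++j) {
    fvec z = Z.col(j);
    z -= z.max();
    z = arma::exp(z);
    Z.col(j) = z / arma::accu(z);
  }
  return Z;
}

// dense head forward: probabilities + hidden activations
static fmat head_forward(const fmat& F, const Params& p, fmat& Dn) {
  Dn = p.W3 * F;
  Dn.each_col() += p.b3;
  relu_inplace(Dn, Dn.n_cols);
  fmat Z = p.W4 * Dn;
  Z.each_col() += p.b4;
  return softmax_cols(Z);
}

struct Adam {
  fmat mW1, vW1, mW2, vW2, mW3, vW3, mW4, vW4;
  fvec mb1, vb1, mb2, vb2, mb3, vb3, mb4, vb4;
  long t = 0;
  void init(const Params& p) {
    mW1.zeros(arma::size(p.W1)); vW1.zeros(arma::size(p.W1));
    mW2.zeros(arma::size(p.W2)); vW2.zeros(arma::size(p.W2));
    mW3.zeros(arma::size(p.W3)); vW3.zeros(arma::size(p.W3));
    mW4.zeros(arma::size(p.W4)); vW4.zeros(arma::size(p.W4));
    mb1.zeros(arma::size(p.b1)); vb1.zeros(arma::size(p.b1));
    mb2.zeros(arma::size(p.b2)); vb2.zeros(arma::size(p.b2));
    mb3.zeros(arma::size(p.b3)); vb3.zeros(arma::size(p.b3));
    mb4.zeros(arma::size(p.b4)); vb4.zeros(arma::size(p.b4));
  }
  template <class M>
  void upd(M& w, M& m, M& v, const M& g, float lr) {
    m = 0.9f * m + 0.1f * g;
    v = 0.999f * v + 0.001f * (g % g);
    float c1 = 1.0f - std::pow(0.9f, (float)t);
    float c2 = 1.0f - std::pow(0.999f, (float)t);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + 1e-7f);
  }
};

// Train on the images selected by train_idx (0-based columns of X) with
// one-pass-per-epoch minibatches; evaluates val_idx after each epoch.
// Returns trained weights and a per-epoch history matrix.
// [[Rcpp::export]]
List cpp_cnn_train(NumericVector X, IntegerVector y, List weights,
                   IntegerVector train_idx, IntegerVector val_idx,
                   int epochs, int batch_size, double lr, double rescale,
                   int shuffle_seed) {
  IntegerVector xd = X.attr("dim");
  if (xd.size() != 4) stop("crop array must be (H, W, C, N)");
  const int H = xd[0], W = xd[1], C = xd[2];
  Params p = params_from_list(weights);
  Dims d = make_dims(H, W, C, (int)p.W1.n_rows, (int)p.W2.n_rows,
                     (int)p.W3.n_rows);
  if ((int)p.W3.n_cols != d.D) stop("weight shapes do not match input shape");
  const size_t imsz = (size_t)H * W * C;
  const double* xp = X.begin();
  const float lrf = (float)lr, rsc = (float)rescale;

  Adam opt;
  opt.init(p);
  SimRng shuf((uint64_t)(uint32_t)shuffle_seed);

  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> vi(val_idx.begin(), val_idx.end());
  const int ntr = (int)tr.size();
  NumericMatrix hist(epochs, 4);

  BatchWork wk;
  wk.init(d, batch_size, true);
  fmat Dn, dF;

  auto eval_set = [&](const std::vector<int>& idx, double& loss,
                      double& acc) {
    double L = 0.0;
    int ok = 0;
    const int n = (int)idx.size();
    for (int start = 0; start < n; start += batch_size) {
      const int B = std::min(batch_size, n - start);
      forward_conv(xp, imsz, idx, start, B, d, p, rsc, wk);
      fmat P = head_forward(wk.F.head_cols(B), p, Dn);
      for (int b = 0; b < B; ++b) {
        int lab = y[idx[start + b]];
        L += -std::log(std::max((double)P(lab, b), 1e-12));
        int hat = (P(0, b) >= P(1, b)) ? 0 : 1;  // ties -> native
        if (hat == lab) ++ok;
      }
    }
    loss = L / n;
    acc = (double)ok / n;
  };

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle with our own RNG (platform-stable)
    for (int i = ntr - 1; i > 0; --i) {
      int j = (int)(shuf.unif() * (i + 1));
      if (j > i) j = i;
      std::swap(tr[i], tr[j]);
    }
    double ep_loss = 0.0;
    long ep_ok = 0;
    for (int start = 0; start < ntr; start += batch_size) {
      const int B = std::min(batch_size, ntr - start);
      forward_conv(xp, imsz, tr, start, B, d, p, rsc, wk);
      fmat Fb = wk.F.head_cols(B);
      fmat P = head_forward(Fb, p, Dn);

      for (int b = 0; b < B; ++b) {
        int lab = y[tr[start + b]];
        ep_loss += -std::log(std::max((double)P(lab, b), 1e-12));
        int hat = (P(0, b) >= P(1, b)) ? 0 : 1;
        if (hat == lab) ++ep_ok;
      }

      // backward: softmax cross-entropy -> dense head
      fmat dZ = P;
      for (int b = 0; b < B; ++b) dZ(y[tr[start + b]], b) -= 1.0f;
      dZ /= (float)B;
      fmat gW4 = dZ * Dn.t();
      fvec gb4 = arma::sum(dZ, 1);
      fmat dDn = p.W4.t() * dZ;
      {
        const float* dn = Dn.memptr();
        float* g = dDn.memptr();
        for (size_t i = 0; i < dDn.n_elem; ++i)
          if (dn[i] <= 0.0f) g[i] = 0.0f;
      }
      fmat gW3 = dDn * Fb.t();
      fvec gb3 = arma::sum(dDn, 1);
      dF = p.W3.t() * dDn;

      // conv stack backward, batched GEMMs
      const size_t nc2 = (size_t)d.NC2 * B, nc1 = (size_t)d.NC1 * B;
      std::fill(wk.dA2.memptr(), wk.dA2.memptr() + wk.dA2.n_rows * nc2, 0.0f);
      for (int b = 0; b < B; ++b)
        for (int ff = 0; ff < d.F2; ++ff)
          for (int j = 0; j < d.NP2; ++j) {
            float g = dF((size_t)d.NP2 * ff + j, b);
            if (g != 0.0f) {
              arma::uword src = wk.i2(ff, b * d.NP2 + j);
              if (wk.A2(ff, src) > 0.0f) wk.dA2(ff, src) += g;
            }
          }
      fmat gW2 = wk.dA2.head_cols(nc2) * wk.X2.head_cols(nc2).t();
      fvec gb2 = arma::sum(wk.dA2.head_cols(nc2), 1);
      wk.dX2.head_cols(nc2) = p.W2.t() * wk.dA2.head_cols(nc2);
      std::fill(wk.dA1.memptr(), wk.dA1.memptr() + wk.dA1.n_rows * nc1, 0.0f);
      for (int b = 0; b < B; ++b) {
        col2im(wk.dX2, b * d.NC2, d.PH1, d.PW1, d.F1, wk.dp1img.data());
        for (int f = 0; f < d.F1; ++f) {
          const float* src = wk.dp1img.data() + (size_t)d.NP1 * f;
          for (int j = 0; j < d.NP1; ++j) {
            float g = src[j];
            if (g != 0.0f) {
              arma::uword si = wk.i1(f, b * d.NP1 + j);
              if (wk.A1(f, si) > 0.0f) wk.dA1(f, si) += g;
            }
          }
        }
      }
      fmat gW1 = wk.dA1.head_cols(nc1) * wk.X1.head_cols(nc1).t();
      fvec gb1 = arma::sum(wk.dA1.head_cols(nc1), 1);

      opt.t += 1;
      opt.upd(p.W1, opt.mW1, opt.vW1, gW1, lrf);
      opt.upd(p.W2, opt.mW2, opt.vW2, gW2, lrf);
      opt.upd(p.W3, opt.mW3, opt.vW3, gW3, lrf);
      opt.upd(p.W4, opt.mW4, opt.vW4, gW4, lrf);
      opt.upd(p.b1, opt.mb1, opt.vb1, gb1, lrf);
      opt.upd(p.b2, opt.mb2, opt.vb2, gb2, lrf);
      opt.upd(p.b3, opt.mb3, opt.vb3, gb3, lrf);
      opt.upd(p.b4, opt.mb4, opt.vb4, gb4, lrf);
      Rcpp::checkUserInterrupt();
    }
    hist(ep, 0) = ep_loss / ntr;
    hist(ep, 1) = (double)ep_ok / ntr;
    if (!vi.empty()) {
      double vl, va;
      eval_set(vi, vl, va);
      hist(ep, 2) = vl;
      hist(ep, 3) = va;
    } else {
      hist(ep, 2) = NA_REAL;
      hist(ep, 3) = NA_REAL;
    }
  }
  colnames(hist) = CharacterVector::create("loss", "accuracy", "val_loss",
                                           "val_accuracy");
  return List::create(_["weights"] = params_to_list(p),
                      _["history"] = hist);
}

// Class probabilities for every image in X. Returns an N x 2 matrix.
// [[Rcpp::export]]
NumericMatrix cpp_cnn_predict(NumericVector X, List weights, double rescale) {
  IntegerVector xd = X.attr("dim");
  if (xd.size() != 4) stop("crop array must be (H, W, C, N)");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  Params p = params_from_list(weights);
  Dims d = make_dims(H, W, C, (int)p.W1.n_rows, (int)p.W2.n_rows,
                     (int)p.W3.n_rows);
  if ((int)p.W3.n_cols != d.D) stop("weight shapes do not match input shape");
  const size_t imsz = (size_t)H * W * C;
  const int B0 = std::min(N, 32);
  BatchWork wk;
  wk.init(d, B0, false);
  fmat Dn;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  NumericMatrix out(N, p.W4.n_rows);
  for (int start = 0; start < N; start += B0) {
    const int B = std::min(B0, N - start);
    forward_conv(X.begin(), imsz, idx, start, B, d, p, (float)rescale, wk);
    fmat pr = head_forward(wk.F.head_cols(B), p, Dn);
    for (int b = 0; b < B; ++b)
      for (arma::uword k = 0; k < pr.n_rows; ++k)
        out(start + b, k) = pr(k, b);
    Rcpp::checkUserInterrupt();
  }
  return out;
}
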