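// Volumetric network kernels: 3x3x3 same-padding convolution (im2col + GEMM,
// slab-chunked along the third spatial axis to bound the im2col buffer),
// 2x2x2/stride-2 max pooling and transpose convolution, ReLU, and the 3^3
// morphological edge extractor used for contour targets.
//
// Compute happens in single precision (converted at the R boundary): the
// GEMMs are memory-bound at these layer widths, and float halves the
// traffic. Array layout follows R column-major order: volumes are
// (D, H, W, C), conv weights (3, 3, 3, Cin, Cout), up-conv weights
// (2, 2, 2, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims4(const NumericVector& x, int& D, int& H, int& W, int& C) {
  IntegerVector d = x.attr("dim");
  if (d.size() < 3) stop("expected an array with >= 3 dimensions");
  D = d[0]; H = d[1]; W = d[2];
  C = (d.size() > 3) ? d[3] : 1;
}

static arma::fvec to_f(const NumericVector& x) {
  arma::fvec out(x.size());
  const double* p = x.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = (float)p[i];
  return out;
}

static NumericVector to_d(const float* x, size_t n, IntegerVector dim) {
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = (double)x[i];
  out.attr("dim") = dim;
  return out;
}

// Number of third-axis slices per im2col slab, capped near 24 MB of floats.
static int slab_size(int D, int H, int cols) {
  double per_slice = (double)D * H * cols;
  return (int)std::max(1.0, std::floor(6.0e6 / std::max(1.0, per_slice)));
}

// Fill im2col slab for output slices [k0, k1): rows r = i + D*(j + H*(k-k0)).
static void fill_im2col(arma::fmat& M, const float* xp,
                        int D, int H, int W, int Cin, int k0, int k1) {
  for (int ci = 0; ci < Cin; ++ci) {
    for (int c = -1; c <= 1; ++c) {
      for (int b = -1; b <= 1; ++b) {
        for (int a = -1; a <= 1; ++a) {
          int col = (a + 1) + 3 * (b + 1) + 9 * (c + 1) + 27 * ci;
          float* Mcol = M.colptr(col);
          for (int k = k0; k < k1; ++k) {
            int kk = k + c;
            for (int j = 0; j < H; ++j) {
              int jj = j + b;
              float* dst = Mcol + (size_t)(k - k0) * D * H + (size_t)j * D;
              if (kk < 0 || kk >= W || jj < 0 || jj >= H) {
                std::fill(dst, dst + D, 0.0f);
                continue;
              }
              const float* src = xp + (((size_t)ci * W + kk) * H + jj) * D;
              if (a == 0) {
                std::copy(src, src + D, dst);
              } else if (a == 1) {
                std::copy(src + 1, src + D, dst);
                dst[D - 1] = 0.0f;
              } else {
                dst[0] = 0.0f;
                std::copy(src, src + D - 1, dst + 1);
              }
            }
          }
        }
      }
    }
  }
}

// Core convolution on float buffers; out must hold D*H*W*Cout floats.
static void conv3d_run(const float* xp, const arma::fmat& W2,
                       const float* bias, float* out,
                       int D, int H, int W, int Cin, int Cout) {
  int slab = slab_size(D, H, 27 * Cin);
  arma::fmat M;
  for (int k0 = 0; k0 < W; k0 += slab) {
    int k1 = std::min(W, k0 + slab);
    size_t rows = (size_t)D * H * (k1 - k0);
    M.set_size(rows, 27 * Cin);
    fill_im2col(M, xp, D, H, W, Cin, k0, k1);
    arma::fmat Y = M * W2;
    for (int co = 0; co < Cout; ++co) {
      float* op = out + (size_t)co * D * H * W + (size_t)k0 * D * H;
      const float* yp = Y.colptr(co);
      float bb = bias ? bias[co] : 0.0f;
      for (size_t r = 0; r < rows; ++r) op[r] = yp[r] + bb;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int D, H, W, Cin; dims4(x, D, H, W, Cin);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 5 || wd[0] != 3 || wd[1] != 3 || wd[2] != 3 || wd[3] != Cin)
    stop("conv weight must be (3,3,3,Cin,Cout) matching input channels");
  int Cout = wd[4];
  arma::fvec xf = to_f(x), wf = to_f(w), bf = to_f(b);
  arma::fmat W2(wf.memptr(), 27 * Cin, Cout, false, true);
  arma::fvec out((size_t)D * H * W * Cout);
  conv3d_run(xf.memptr(), W2, bf.memptr(), out.memptr(), D, H, W, Cin, Cout);
  return to_d(out.memptr(), out.n_elem,
              IntegerVector::create(D, H, W, Cout));
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    bool need_gx) {
  int D, H, W, Cin; dims4(x, D, H, W, Cin);
  IntegerVector wd = w.attr("dim");
  int Cout = wd[4];
  size_t N = (size_t)D * H * W;
  arma::fvec xf = to_f(x), wf = to_f(w), gyf = to_f(gy);

  // weight gradient: GW = sum_slabs im2col(x)^T * GY; bias: column sums
  arma::fmat GW(27 * Cin, Cout, arma::fill::zeros);
  NumericVector gb(Cout);
  {
    int slab = slab_size(D, H, 27 * Cin);
    arma::fmat M;
    for (int k0 = 0; k0 < W; k0 += slab) {
      int k1 = std::min(W, k0 + slab);
      size_t rows = (size_t)D * H * (k1 - k0);
      M.set_size(rows, 27 * Cin);
      fill_im2col(M, xf.memptr(), D, H, W, Cin, k0, k1);
      arma::fmat GY(rows, Cout);
      for (int co = 0; co < Cout; ++co) {
        const float* src = gyf.memptr() + (size_t)co * N + (size_t)k0 * D * H;
        std::copy(src, src + rows, GY.colptr(co));
        double s = 0; for (size_t r = 0; r < rows; ++r) s += src[r];
        gb[co] += s;
      }
      GW += M.t() * GY;
    }
  }
  NumericVector gw(27 * (size_t)Cin * Cout);
  for (size_t i = 0; i < gw.size(); ++i) gw[i] = (double)GW.memptr()[i];
  gw.attr("dim") = wd;

  NumericVector gx;
  if (need_gx) {
    // input gradient is itself a convolution of gy with the spatially
    // flipped kernel and swapped channel roles
    arma::fvec wflip((size_t)27 * Cout * Cin);
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        for (int o = 0; o < 27; ++o) {
          float v = wf[(size_t)o + 27 * ci + (size_t)27 * Cin * co];
          wflip[(size_t)(26 - o) + 27 * co + (size_t)27 * Cout * ci] = v;
        }
    arma::fmat W2f(wflip.memptr(), 27 * Cout, Cin, false, true);
    arma::fvec gxf(N * Cin);
    conv3d_run(gyf.memptr(), W2f, nullptr, gxf.memptr(), D, H, W, Cout, Cin);
    gx = to_d(gxf.memptr(), gxf.n_elem, IntegerVector::create(D, H, W, Cin));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x) {
  int D, H, W, C; dims4(x, D, H, W, C);
  if (D % 2 || H % 2 || W % 2) stop("max-pooling requires even spatial dims");
  int Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Do * Ho * Wo * C);
  IntegerVector idx((size_t)Do * Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  const double* xp = x.begin();
  size_t r = 0;
  for (int c = 0; c < C; ++c) {
    size_t coff = (size_t)c * D * H * W;
    for (int k = 0; k < Wo; ++k)
      for (int j = 0; j < Ho; ++j)
        for (int i = 0; i < Do; ++i, ++r) {
          double best = -std::numeric_limits<double>::infinity();
          size_t barg = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                size_t lin = coff + (((size_t)(2 * k + dk) * H) + (2 * j + dj)) * D
                             + (2 * i + di);
                double v = xp[lin];
                if (v > best) { best = v; barg = lin; }
              }
          out[r] = best;
          idx[r] = (int)barg;
        }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(IntegerVector idx, NumericVector gy,
                                IntegerVector in_dim) {
  size_t n = 1;
  for (int i = 0; i < in_dim.size(); ++i) n *= (size_t)in_dim[i];
  NumericVector gx(n);
  gx.attr("dim") = in_dim;
  for (R_xlen_t r = 0; r < gy.size(); ++r) gx[idx[r]] += gy[r];
  return gx;
}

// Transpose convolution, kernel 2^3 stride 2: every output voxel receives
// exactly one (input voxel, offset) contribution, so forward is 8 GEMMs.
// [[Rcpp::export]]
NumericVector cpp_upconv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int D, H, W, Cin; dims4(x, D, H, W, Cin);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 5 || wd[0] != 2 || wd[3] != Cin)
    stop("up-conv weight must be (2,2,2,Cin,Cout)");
  int Cout = wd[4];
  size_t N = (size_t)D * H * W;
  arma::fvec xf = to_f(x), wf = to_f(w);
  arma::fmat X(xf.memptr(), N, Cin, false, true);
  arma::fvec outf(8 * N * Cout);
  int Do = 2 * D, Ho = 2 * H;
  for (int c = 0; c < 2; ++c)
    for (int b2 = 0; b2 < 2; ++b2)
      for (int a = 0; a < 2; ++a) {
        arma::fmat Wo(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wo(ci, co) = wf[a + 2 * b2 + 4 * c + 8 * ci + (size_t)8 * Cin * co];
        arma::fmat Y = X * Wo;
        for (int co = 0; co < Cout; ++co) {
          const float* yp = Y.colptr(co);
          float bb = (float)b[co];
          size_t r = 0;
          for (int k = 0; k < W; ++k)
            for (int j = 0; j < H; ++j) {
              size_t base = ((size_t)co * 2 * W + (2 * k + c)) * Ho;
              base = (base + (2 * j + b2)) * Do + a;
              for (int i = 0; i < D; ++i, ++r)
                outf[base + 2 * i] = yp[r] + bb;
            }
        }
      }
  return to_d(outf.memptr(), outf.n_elem,
              IntegerVector::create(2 * D, 2 * H, 2 * W, Cout));
}

// [[Rcpp::export]]
List cpp_upconv3d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  int D, H, W, Cin; dims4(x, D, H, W, Cin);
  IntegerVector wd = w.attr("dim");
  int Cout = wd[4];
  size_t N = (size_t)D * H * W;
  arma::fvec xf = to_f(x), wf = to_f(w), gyf = to_f(gy);
  arma::fmat X(xf.memptr(), N, Cin, false, true);
  arma::fmat GX(N, Cin, arma::fill::zeros);
  NumericVector gw((size_t)8 * Cin * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  int Do = 2 * D, Ho = 2 * H;
  for (int c = 0; c < 2; ++c)
    for (int b2 = 0; b2 < 2; ++b2)
      for (int a = 0; a < 2; ++a) {
        arma::fmat GY(N, Cout);
        for (int co = 0; co < Cout; ++co) {
          float* dst = GY.colptr(co);
          size_t r = 0;
          double s = 0;
          for (int k = 0; k < W; ++k)
            for (int j = 0; j < H; ++j) {
              size_t base = ((size_t)co * 2 * W + (2 * k + c)) * Ho;
              base = (base + (2 * j + b2)) * Do + a;
              for (int i = 0; i < D; ++i, ++r) {
                dst[r] = gyf[base + 2 * i];
                s += dst[r];
              }
            }
          gb[co] += s;
        }
        arma::fmat Wo(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wo(ci, co) = wf[a + 2 * b2 + 4 * c + 8 * ci + (size_t)8 * Cin * co];
        GX += GY * Wo.t();
        arma::fmat GWo = X.t() * GY;
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            gw[a + 2 * b2 + 4 * c + 8 * ci + (size_t)8 * Cin * co] =
              (double)GWo(ci, co);
      }
  NumericVector gx(GX.n_elem);
  for (size_t i = 0; i < GX.n_elem; ++i) gx[i] = (double)GX.memptr()[i];
  gx.attr("dim") = IntegerVector::create(D, H, W, Cin);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_relu(NumericVector x) {
  NumericVector out(x.size());
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) op[i] = xp[i] > 0 ? xp[i] : 0.0;
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector g, NumericVector a) {
  NumericVector out(g.size());
  const double* gp = g.begin();
  const double* ap = a.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) op[i] = ap[i] > 0 ? gp[i] : 0.0;
  out.attr("dim") = g.attr("dim");
  return out;
}

// Per-class morphological gradient with a 3^3 structuring element: a voxel is
// an edge voxel of class k if its 3^3 neighbourhood contains both class-k and
// non-class-k voxels. Overlaps resolve to the lower class index.
// [[Rcpp::export]]
IntegerVector cpp_morph_edges(IntegerVector lab, int n_classes) {
  IntegerVector d = lab.attr("dim");
  int D = d[0], H = d[1], W = d[2];
  IntegerVector out((size_t)D * H * W);
  out.attr("dim") = d;
  const int* lp = lab.begin();
  size_t r = 0;
  for (int k = 0; k < W; ++k)
    for (int j = 0; j < H; ++j)
      for (int i = 0; i < D; ++i, ++r) {
        bool has[16] = {false};
        bool other[16] = {false};
        for (int dk = -1; dk <= 1; ++dk) {
          int kk = k + dk; if (kk < 0 || kk >= W) continue;
          for (int dj = -1; dj <= 1; ++dj) {
            int jj = j + dj; if (jj < 0 || jj >= H) continue;
            for (int di = -1; di <= 1; ++di) {
              int ii = i + di; if (ii < 0 || ii >= D) continue;
              int v = lp[((size_t)kk * H + jj) * D + ii];
              for (int cls = 1; cls < n_classes; ++cls) {
                if (v == cls) has[cls] = true; else other[cls] = true;
              }
            }
          }
        }
        int e = 0;
        for (int cls = 1; cls < n_classes; ++cls)
          if (has[cls] && other[cls]) { e = cls; break; }
        out[r] = e;
      }
  return out;
}
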