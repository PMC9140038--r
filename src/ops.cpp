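// Numerical core: convolution (im2col + BLAS dgemm), bilinear/nearest
// warping, 2x resampling, and bilinear resize. All arrays are R column-major
// doubles; images are (H, W, C) and displacement fields are (H, W, 2) with
// component 1 = dy (rows) and component 2 = dx (cols), in pixels.
#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Gather input patches into A: (Ho*Wo) x (k*k*Cin), column index
// ki + k*kj + k*k*ci matching the (k, k, Cin, Cout) weight layout.
static void im2col(const double* x, int H, int W, int Cin, int k, int stride,
                   int pad, int Ho, int Wo, double* A) {
  const int M = Ho * Wo;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)H * W * ci;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* Acol = A + (size_t)M * (ki + k * kj + k * k * ci);
        for (int co = 0; co < Wo; ++co) {
          int cin = co * stride - pad + kj;
          bool cok = (cin >= 0 && cin < W);
          for (int ro = 0; ro < Ho; ++ro) {
            int rin = ro * stride - pad + ki;
            double v = 0.0;
            if (cok && rin >= 0 && rin < H) v = xc[rin + (size_t)H * cin];
            Acol[ro + (size_t)Ho * co] = v;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("conv2d: weight dims do not match input");
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  const int M = Ho * Wo, K = k * k * Cin;
  std::vector<double> A((size_t)M * K);
  im2col(REAL(x), H, W, Cin, k, stride, pad, Ho, Wo, A.data());
  NumericVector y((size_t)M * Cout);
  double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &M, &Cout, (int*)&K, &one, A.data(), (int*)&M,
                  REAL(w), (int*)&K, &zero, REAL(y), (int*)&M FCONE FCONE);
  double* yp = REAL(y);
  const double* bp = REAL(b);
  for (int co = 0; co < Cout; ++co)
    for (int i = 0; i < M; ++i) yp[i + (size_t)M * co] += bp[co];
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return y;
}

// Forward convolution that also returns the im2col matrix for reuse in the
// backward pass.
// [[Rcpp::export]]
List conv2d_fwA_cpp(NumericVector x, NumericVector w, NumericVector b,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int k = wd[0], Cout = wd[3];
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  const int M = Ho * Wo, K = k * k * Cin;
  NumericMatrix A(M, K);
  im2col(REAL(x), H, W, Cin, k, stride, pad, Ho, Wo, REAL(A));
  NumericVector y((size_t)M * Cout);
  double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &M, &Cout, (int*)&K, &one, REAL(A), (int*)&M,
                  REAL(w), (int*)&K, &zero, REAL(y), (int*)&M FCONE FCONE);
  double* yp = REAL(y);
  const double* bp = REAL(b);
  for (int co = 0; co < Cout; ++co)
    for (int i = 0; i < M; ++i) yp[i + (size_t)M * co] += bp[co];
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return List::create(_["y"] = y, _["A"] = A);
}

// Backward pass using a cached im2col matrix; gx is skipped when not needed
// (first encoder layer: the inputs are data, not parameters).
// [[Rcpp::export]]
List conv2d_bwA_cpp(NumericMatrix A, NumericVector w, NumericVector gy,
                    int H, int W, int stride, int pad, bool want_gx) {
  IntegerVector wd = w.attr("dim"), gd = gy.attr("dim");
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  const int M = Ho * Wo, K = k * k * Cin;
  NumericVector gw((size_t)K * Cout), gb(Cout);
  double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("T", "N", (int*)&K, &Cout, (int*)&M, &one, REAL(A),
                  (int*)&M, REAL(gy), (int*)&M, &zero, REAL(gw),
                  (int*)&K FCONE FCONE);
  const double* gp = REAL(gy);
  for (int co = 0; co < Cout; ++co) {
    double s = 0.0;
    for (int i = 0; i < M; ++i) s += gp[i + (size_t)M * co];
    gb[co] = s;
  }
  gw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  if (!want_gx)
    return List::create(_["gw"] = gw, _["gb"] = gb);
  std::vector<double> Gcol((size_t)M * K);
  F77_CALL(dgemm)("N", "T", (int*)&M, (int*)&K, &Cout, &one, REAL(gy),
                  (int*)&M, REAL(w), (int*)&K, &zero, Gcol.data(),
                  (int*)&M FCONE FCONE);
  NumericVector gx((size_t)H * W * Cin);
  double* gxp = REAL(gx);
  for (int ci = 0; ci < Cin; ++ci) {
    double* gxc = gxp + (size_t)H * W * ci;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* Gc = Gcol.data() + (size_t)M * (ki + k * kj + k * k * ci);
        for (int co = 0; co < Wo; ++co) {
          int cin = co * stride - pad + kj;
          if (cin < 0 || cin >= W) continue;
          for (int ro = 0; ro < Ho; ++ro) {
            int rin = ro * stride - pad + ki;
            if (rin < 0 || rin >= H) continue;
            gxc[rin + (size_t)H * cin] += Gc[ro + (size_t)Ho * co];
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, Cin);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int k = wd[0], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  const int M = Ho * Wo, K = k * k * Cin;
  std::vector<double> A((size_t)M * K);
  im2col(REAL(x), H, W, Cin, k, stride, pad, Ho, Wo, A.data());

  NumericVector gw((size_t)K * Cout), gb(Cout), gx((size_t)H * W * Cin);
  double one = 1.0, zero = 0.0;
  // gw = A^T G
  F77_CALL(dgemm)("T", "N", (int*)&K, &Cout, (int*)&M, &one, A.data(),
                  (int*)&M, REAL(gy), (int*)&M, &zero, REAL(gw),
                  (int*)&K FCONE FCONE);
  const double* gp = REAL(gy);
  for (int co = 0; co < Cout; ++co) {
    double s = 0.0;
    for (int i = 0; i < M; ++i) s += gp[i + (size_t)M * co];
    gb[co] = s;
  }
  // Gcol = G W^T, then scatter-add back to input positions (col2im).
  std::vector<double> Gcol((size_t)M * K);
  F77_CALL(dgemm)("N", "T", (int*)&M, (int*)&K, &Cout, &one, REAL(gy),
                  (int*)&M, REAL(w), (int*)&K, &zero, Gcol.data(),
                  (int*)&M FCONE FCONE);
  double* gxp = REAL(gx);
  for (int ci = 0; ci < Cin; ++ci) {
    double* gxc = gxp + (size_t)H * W * ci;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* Gc = Gcol.data() + (size_t)M * (ki + k * kj + k * k * ci);
        for (int co = 0; co < Wo; ++co) {
          int cin = co * stride - pad + kj;
          if (cin < 0 || cin >= W) continue;
          for (int ro = 0; ro < Ho; ++ro) {
            int rin = ro * stride - pad + ki;
            if (rin < 0 || rin >= H) continue;
            gxc[rin + (size_t)H * cin] += Gc[ro + (size_t)Ho * co];
          }
        }
      }
    }
  }
  gw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  gx.attr("dim") = IntegerVector::create(H, W, Cin);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector upsample2_fw_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        yp[i + (size_t)Ho * j + (size_t)Ho * Wo * c] =
            xp[(i / 2) + (size_t)H * (j / 2) + (size_t)H * W * c];
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bw_cpp(NumericVector gy) {
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1], C = gd[2];
  int H = Ho / 2, W = Wo / 2;
  NumericVector gx((size_t)H * W * C);
  const double* gp = REAL(gy);
  double* xp = REAL(gx);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        xp[(i / 2) + (size_t)H * (j / 2) + (size_t)H * W * c] +=
            gp[i + (size_t)Ho * j + (size_t)Ho * Wo * c];
  gx.attr("dim") = IntegerVector::create(H, W, C);
  return gx;
}

// Direct (im2col-free) 2-d convolution; all planes stay cache-resident for
// the layer sizes this network uses. Column-major (H, W, C) layout.
// [[Rcpp::export]]
NumericVector conv2d_dfw_cpp(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int k = wd[0], Cout = wd[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * Cout);
  double* yp = REAL(y);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* bp = REAL(b);
  for (int co = 0; co < Cout; ++co) {
    double* ycp = yp + (size_t)Ho * Wo * co;
    const double bv = bp[co];
    for (size_t i = 0; i < (size_t)Ho * Wo; ++i) ycp[i] = bv;
  }
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = xp + (size_t)H * W * ci;
    for (int co = 0; co < Cout; ++co) {
      double* yc = yp + (size_t)Ho * Wo * co;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const double wv = wp[ki + k * kj + k * k * ci + k * k * Cin * co];
          if (wv == 0.0) continue;
          for (int c0 = 0; c0 < Wo; ++c0) {
            const int cin = c0 * stride - pad + kj;
            if (cin < 0 || cin >= W) continue;
            const double* xcol = xc + (size_t)H * cin;
            double* ycol = yc + (size_t)Ho * c0;
            // rows with rin = r0*stride - pad + ki inside [0, H)
            int r0lo = 0;
            while (r0lo * stride - pad + ki < 0) ++r0lo;
            int r0hi = Ho - 1;
            while (r0hi * stride - pad + ki >= H) --r0hi;
            const int off = -pad + ki;
            if (stride == 1) {
              const double* xs = xcol + off;
              for (int r0 = r0lo; r0 <= r0hi; ++r0) ycol[r0] += wv * xs[r0];
            } else {
              for (int r0 = r0lo; r0 <= r0hi; ++r0)
                ycol[r0] += wv * xcol[r0 * stride + off];
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return y;
}

// Direct backward: gw, gb and (optionally) gx in one pass over the data.
// [[Rcpp::export]]
List conv2d_dbw_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, bool want_gx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int k = wd[0], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  NumericVector gw((size_t)k * k * Cin * Cout), gb(Cout);
  NumericVector gx(want_gx ? (size_t)H * W * Cin : 1);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* gp = REAL(gy);
  double* gwp = REAL(gw);
  double* gbp = REAL(gb);
  double* gxp = REAL(gx);
  if (want_gx) std::fill(gxp, gxp + (size_t)H * W * Cin, 0.0);
  for (int co = 0; co < Cout; ++co) {
    const double* gc = gp + (size_t)Ho * Wo * co;
    double s = 0.0;
    for (size_t i = 0; i < (size_t)Ho * Wo; ++i) s += gc[i];
    gbp[co] = s;
  }
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = xp + (size_t)H * W * ci;
    double* gxc = want_gx ? gxp + (size_t)H * W * ci : nullptr;
    for (int co = 0; co < Cout; ++co) {
      const double* gc = gp + (size_t)Ho * Wo * co;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const double wv = wp[ki + k * kj + k * k * ci + k * k * Cin * co];
          double acc = 0.0;
          for (int c0 = 0; c0 < Wo; ++c0) {
            const int cin = c0 * stride - pad + kj;
            if (cin < 0 || cin >= W) continue;
            const double* xcol = xc + (size_t)H * cin;
            double* gxcol = want_gx ? gxc + (size_t)H * cin : nullptr;
            const double* gcol = gc + (size_t)Ho * c0;
            int r0lo = 0;
            while (r0lo * stride - pad + ki < 0) ++r0lo;
            int r0hi = Ho - 1;
            while (r0hi * stride - pad + ki >= H) --r0hi;
            const int off = -pad + ki;
            if (stride == 1) {
              const double* xs = xcol + off;
              if (want_gx) {
                double* gs = gxcol + off;
                for (int r0 = r0lo; r0 <= r0hi; ++r0) {
                  acc += gcol[r0] * xs[r0];
                  gs[r0] += wv * gcol[r0];
                }
              } else {
                for (int r0 = r0lo; r0 <= r0hi; ++r0) acc += gcol[r0] * xs[r0];
              }
            } else {
              if (want_gx) {
                for (int r0 = r0lo; r0 <= r0hi; ++r0) {
                  const int rin = r0 * stride + off;
                  acc += gcol[r0] * xcol[rin];
                  gxcol[rin] += wv * gcol[r0];
                }
              } else {
                for (int r0 = r0lo; r0 <= r0hi; ++r0)
                  acc += gcol[r0] * xcol[r0 * stride + off];
              }
            }
          }
          gwp[ki + k * kj + k * k * ci + k * k * Cin * co] = acc;
        }
      }
    }
  }
  gw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  if (want_gx) {
    gx.attr("dim") = IntegerVector::create(H, W, Cin);
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

// In-place leaky ReLU; the output keeps the sign pattern of the input, so
// the backward pass can recover the activation mask from the output alone.
// [[Rcpp::export]]
NumericVector lrelu_fw_cpp(NumericVector z, double slope) {
  double* p = REAL(z);
  const R_xlen_t n = z.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (p[i] < 0) p[i] *= slope;
  return z;
}

// gz = g * (y >= 0 ? 1 : slope), reading the activated output y.
// [[Rcpp::export]]
NumericVector lrelu_bw_cpp(NumericVector y, NumericVector g, double slope) {
  NumericVector gz(clone(g));
  double* gp = REAL(gz);
  const double* yp = REAL(y);
  const R_xlen_t n = gz.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (yp[i] < 0) gp[i] *= slope;
  gz.attr("dim") = g.attr("dim");
  return gz;
}

// [[Rcpp::export]]
NumericVector concat_ch_cpp(NumericVector a, NumericVector b) {
  IntegerVector da = a.attr("dim"), db = b.attr("dim");
  const size_t na = a.size(), nb = b.size();
  NumericVector out(na + nb);
  std::copy(REAL(a), REAL(a) + na, REAL(out));
  std::copy(REAL(b), REAL(b) + nb, REAL(out) + na);
  out.attr("dim") = IntegerVector::create(da[0], da[1], da[2] + db[2]);
  return out;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Backward warp with clamp-to-edge bilinear sampling:
// out(r, c) = img(r + dy(r,c), c + dx(r,c)).
// [[Rcpp::export]]
NumericVector warp_bilinear_fw_cpp(NumericVector img, NumericVector field) {
  IntegerVector id = img.attr("dim"), fd = field.attr("dim");
  int H = id[0], W = id[1];
  int C = (id.size() == 3) ? (int)id[2] : 1;
  if (fd[0] != H || fd[1] != W) stop("warp: field/image dimension mismatch");
  NumericVector out((size_t)H * W * C);
  const double* ip = REAL(img);
  const double* fp = REAL(field);
  double* op = REAL(out);
  const size_t plane = (size_t)H * W;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      size_t p = r + (size_t)H * c;
      double sr = clampd(r + fp[p], 0.0, H - 1.0);
      double sc = clampd(c + fp[p + plane], 0.0, W - 1.0);
      int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      if (r0 > H - 2) r0 = H - 2;
      if (c0 > W - 2) c0 = W - 2;
      if (r0 < 0) r0 = 0;
      if (c0 < 0) c0 = 0;
      double fr = sr - r0, fc = sc - c0;
      for (int ch = 0; ch < C; ++ch) {
        const double* im = ip + plane * ch;
        double v00 = im[r0 + (size_t)H * c0];
        double v10 = im[r0 + 1 + (size_t)H * c0];
        double v01 = im[r0 + (size_t)H * (c0 + 1)];
        double v11 = im[r0 + 1 + (size_t)H * (c0 + 1)];
        op[p + plane * ch] = (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
                             (1 - fr) * fc * v01 + fr * fc * v11;
      }
    }
  }
  if (id.size() == 3)
    out.attr("dim") = IntegerVector::create(H, W, C);
  else
    out.attr("dim") = IntegerVector::create(H, W);
  return out;
}

// [[Rcpp::export]]
List warp_bilinear_bw_cpp(NumericVector img, NumericVector field,
                          NumericVector gout) {
  IntegerVector id = img.attr("dim");
  int H = id[0], W = id[1];
  int C = (id.size() == 3) ? (int)id[2] : 1;
  NumericVector gimg((size_t)H * W * C), gfield((size_t)H * W * 2);
  const double* ip = REAL(img);
  const double* fp = REAL(field);
  const double* gp = REAL(gout);
  double* gi = REAL(gimg);
  double* gf = REAL(gfield);
  const size_t plane = (size_t)H * W;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      size_t p = r + (size_t)H * c;
      double sr0 = r + fp[p], sc0 = c + fp[p + plane];
      bool rcl = (sr0 <= 0.0 || sr0 >= H - 1.0);
      bool ccl = (sc0 <= 0.0 || sc0 >= W - 1.0);
      double sr = clampd(sr0, 0.0, H - 1.0), sc = clampd(sc0, 0.0, W - 1.0);
      int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      if (r0 > H - 2) r0 = H - 2;
      if (c0 > W - 2) c0 = W - 2;
      if (r0 < 0) r0 = 0;
      if (c0 < 0) c0 = 0;
      double fr = sr - r0, fc = sc - c0;
      double gdy = 0.0, gdx = 0.0;
      for (int ch = 0; ch < C; ++ch) {
        const double* im = ip + plane * ch;
        double g = gp[p + plane * ch];
        if (g == 0.0) continue;
        size_t i00 = r0 + (size_t)H * c0, i10 = i00 + 1;
        size_t i01 = r0 + (size_t)H * (c0 + 1), i11 = i01 + 1;
        gi[i00 + plane * ch] += g * (1 - fr) * (1 - fc);
        gi[i10 + plane * ch] += g * fr * (1 - fc);
        gi[i01 + plane * ch] += g * (1 - fr) * fc;
        gi[i11 + plane * ch] += g * fr * fc;
        double dvr = (1 - fc) * (im[i10] - im[i00]) + fc * (im[i11] - im[i01]);
        double dvc = (1 - fr) * (im[i01] - im[i00]) + fr * (im[i11] - im[i10]);
        if (!rcl) gdy += g * dvr;
        if (!ccl) gdx += g * dvc;
      }
      gf[p] = gdy;
      gf[p + plane] = gdx;
    }
  }
  if (id.size() == 3)
    gimg.attr("dim") = IntegerVector::create(H, W, C);
  else
    gimg.attr("dim") = IntegerVector::create(H, W);
  gfield.attr("dim") = IntegerVector::create(H, W, 2);
  return List::create(_["gimg"] = gimg, _["gfield"] = gfield);
}

// Nearest-neighbour backward warp; keeps label images strictly binary.
// [[Rcpp::export]]
NumericVector warp_nearest_cpp(NumericVector img, NumericVector field) {
  IntegerVector id = img.attr("dim");
  int H = id[0], W = id[1];
  NumericVector out((size_t)H * W);
  const double* ip = REAL(img);
  const double* fp = REAL(field);
  double* op = REAL(out);
  const size_t plane = (size_t)H * W;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      size_t p = r + (size_t)H * c;
      int sr = (int)std::lround(clampd(r + fp[p], 0.0, H - 1.0));
      int sc = (int)std::lround(clampd(c + fp[p + plane], 0.0, W - 1.0));
      op[p] = ip[sr + (size_t)H * sc];
    }
  }
  out.attr("dim") = IntegerVector::create(H, W);
  return out;
}

// Pixel-centre-aligned bilinear resize, clamp-to-edge.
// [[Rcpp::export]]
NumericVector resize_bilinear_cpp(NumericVector img, int Ho, int Wo) {
  IntegerVector id = img.attr("dim");
  int H = id[0], W = id[1];
  int C = (id.size() == 3) ? (int)id[2] : 1;
  NumericVector out((size_t)Ho * Wo * C);
  const double* ip = REAL(img);
  double* op = REAL(out);
  double sy = (double)H / Ho, sx = (double)W / Wo;
  const size_t plane = (size_t)H * W;
  for (int c = 0; c < Wo; ++c) {
    double scc = clampd((c + 0.5) * sx - 0.5, 0.0, W - 1.0);
    int c0 = (int)std::floor(scc);
    if (c0 > W - 2) c0 = W - 2;
    if (c0 < 0) c0 = 0;
    double fc = scc - c0;
    for (int r = 0; r < Ho; ++r) {
      double srr = clampd((r + 0.5) * sy - 0.5, 0.0, H - 1.0);
      int r0 = (int)std::floor(srr);
      if (r0 > H - 2) r0 = H - 2;
      if (r0 < 0) r0 = 0;
      double fr = srr - r0;
      for (int ch = 0; ch < C; ++ch) {
        const double* im = ip + plane * ch;
        double v = (1 - fr) * (1 - fc) * im[r0 + (size_t)H * c0] +
                   fr * (1 - fc) * im[r0 + 1 + (size_t)H * c0] +
                   (1 - fr) * fc * im[r0 + (size_t)H * (c0 + 1)] +
                   fr * fc * im[r0 + 1 + (size_t)H * (c0 + 1)];
        op[r + (size_t)Ho * c + (size_t)Ho * Wo * ch] = v;
      }
    }
  }
  if (id.size() == 3)
    out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  else
    out.attr("dim") = IntegerVector::create(Ho, Wo);
  return out;
}
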