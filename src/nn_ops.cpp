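// Low-level tensor kernels for the 3D convolutional network engine and for
// trilinear volume resampling.  Activation tensors use the layout
// [C, X, Y, Z, N] (channel fastest, column-major), so a C-length channel
// column at one spatial location is contiguous.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline R_xlen_t idx4(int c, int x, int y, int z,
                            int C, int X, int Y) {
  return c + (R_xlen_t)C * (x + (R_xlen_t)X * (y + (R_xlen_t)Y * z));
}

// valid output-index range [lo, hi) for one axis and kernel offset: the
// input index o*s - p + c must land in [0, n)
static inline void valid_range(int n, int o_n, int s, int p, int c,
                               int& lo, int& hi) {
  lo = 0;
  while (lo < o_n && lo * s - p + c < 0) ++lo;
  hi = o_n;
  while (hi > lo && (hi - 1) * s - p + c >= n) --hi;
}

// im2col for one sample: K = C*k0*k1*k2 rows, L = OX*OY*OZ columns.
// Row ordering: channel fastest, then kernel x, y, z — matching an R weight
// array of dim c(Cout, Cin, k0, k1, k2) flattened to a Cout x K matrix.
// Padding entries must have been zeroed beforehand (they are identical for
// every sample, so the caller zeroes the buffer once per conv call).
template <typename T>
static void im2col(const T* xs, int C, int X, int Y, int Z,
                   const int* k, const int* s, const int* p,
                   int OX, int OY, int OZ, arma::Mat<T>& cols) {
  const R_xlen_t K = cols.n_rows;
  for (int c2 = 0; c2 < k[2]; ++c2) {
    int loz, hiz; valid_range(Z, OZ, s[2], p[2], c2, loz, hiz);
    for (int c1 = 0; c1 < k[1]; ++c1) {
      int loy, hiy; valid_range(Y, OY, s[1], p[1], c1, loy, hiy);
      for (int c0 = 0; c0 < k[0]; ++c0) {
        int lox, hix; valid_range(X, OX, s[0], p[0], c0, lox, hix);
        R_xlen_t row0 = (R_xlen_t)C * (c0 + (R_xlen_t)k[0] * (c1 + (R_xlen_t)k[1] * c2));
        for (int oz = loz; oz < hiz; ++oz) {
          int z = oz * s[2] - p[2] + c2;
          for (int oy = loy; oy < hiy; ++oy) {
            int y = oy * s[1] - p[1] + c1;
            const T* src = xs + idx4(0, lox * s[0] - p[0] + c0, y, z, C, X, Y);
            T* dst = cols.colptr(lox + (R_xlen_t)OX * (oy + (R_xlen_t)OY * oz)) + row0;
            for (int ox = lox; ox < hix; ++ox) {
              for (int c = 0; c < C; ++c) dst[c] = src[c];
              src += (R_xlen_t)C * s[0];
              dst += K;
            }
          }
        }
      }
    }
  }
}

// zero only the padding entries of the im2col buffer (those outside every
// sample's valid ranges); call once before the per-sample loop
template <typename T>
static void im2col_zero_pad(const int* p, arma::Mat<T>& cols) {
  if (p[0] == 0 && p[1] == 0 && p[2] == 0) return;
  cols.zeros();
}

template <typename T>
static void col2im_add(const arma::Mat<T>& cols, T* xs,
                       int C, int X, int Y, int Z,
                       const int* k, const int* s, const int* p,
                       int OX, int OY, int OZ) {
  const R_xlen_t K = cols.n_rows;
  for (int c2 = 0; c2 < k[2]; ++c2) {
    int loz, hiz; valid_range(Z, OZ, s[2], p[2], c2, loz, hiz);
    for (int c1 = 0; c1 < k[1]; ++c1) {
      int loy, hiy; valid_range(Y, OY, s[1], p[1], c1, loy, hiy);
      for (int c0 = 0; c0 < k[0]; ++c0) {
        int lox, hix; valid_range(X, OX, s[0], p[0], c0, lox, hix);
        R_xlen_t row0 = (R_xlen_t)C * (c0 + (R_xlen_t)k[0] * (c1 + (R_xlen_t)k[1] * c2));
        for (int oz = loz; oz < hiz; ++oz) {
          int z = oz * s[2] - p[2] + c2;
          for (int oy = loy; oy < hiy; ++oy) {
            int y = oy * s[1] - p[1] + c1;
            const T* src = cols.colptr(lox + (R_xlen_t)OX * (oy + (R_xlen_t)OY * oz)) + row0;
            T* dst = xs + idx4(0, lox * s[0] - p[0] + c0, y, z, C, X, Y);
            for (int ox = lox; ox < hix; ++ox) {
              for (int c = 0; c < C; ++c) dst[c] += src[c];
              src += K;
              dst += (R_xlen_t)C * s[0];
            }
          }
        }
      }
    }
  }
}

template <typename T>
static void conv3d_fwd_core(const double* x, double* y,
                            const double* Wp, const double* bp,
                            int C, int X, int Y, int Z, int N, int Cout,
                            const int* k, const int* s, const int* p,
                            int OX, int OY, int OZ) {
  R_xlen_t K = (R_xlen_t)C * k[0] * k[1] * k[2];
  R_xlen_t L = (R_xlen_t)OX * OY * OZ;
  R_xlen_t in_stride = (R_xlen_t)C * X * Y * Z;
  R_xlen_t out_stride = (R_xlen_t)Cout * L;
  arma::Mat<T> W(Cout, K);
  std::copy(Wp, Wp + (R_xlen_t)Cout * K, W.memptr());
  arma::Col<T> bv(Cout);
  std::copy(bp, bp + Cout, bv.memptr());
  arma::Col<T> xs(in_stride);
  arma::Mat<T> cols(K, L);
  im2col_zero_pad(p, cols);
  for (int n = 0; n < N; ++n) {
    std::copy(x + n * in_stride, x + (n + 1) * in_stride, xs.memptr());
    im2col(xs.memptr(), C, X, Y, Z, k, s, p, OX, OY, OZ, cols);
    arma::Mat<T> ym = W * cols;
    ym.each_col() += bv;
    std::copy(ym.memptr(), ym.memptr() + out_stride, y + n * out_stride);
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericMatrix Wm, NumericVector b,
                             IntegerVector kk, IntegerVector ss,
                             IntegerVector pp, bool single = false) {
  int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3], N = xdim[4];
  int k[3] = {kk[0], kk[1], kk[2]};
  int s[3] = {ss[0], ss[1], ss[2]};
  int p[3] = {pp[0], pp[1], pp[2]};
  int Cout = Wm.nrow();
  int OX = (X + 2 * p[0] - k[0]) / s[0] + 1;
  int OY = (Y + 2 * p[1] - k[1]) / s[1] + 1;
  int OZ = (Z + 2 * p[2] - k[2]) / s[2] + 1;
  if (OX < 1 || OY < 1 || OZ < 1)
    stop("conv3d: kernel larger than padded input");
  R_xlen_t K = (R_xlen_t)C * k[0] * k[1] * k[2];
  if ((R_xlen_t)Wm.ncol() != K) stop("conv3d: weight shape mismatch");
  NumericVector y((R_xlen_t)Cout * OX * OY * OZ * N);
  if (single)
    conv3d_fwd_core<float>(x.begin(), y.begin(), Wm.begin(), b.begin(),
                           C, X, Y, Z, N, Cout, k, s, p, OX, OY, OZ);
  else
    conv3d_fwd_core<double>(x.begin(), y.begin(), Wm.begin(), b.begin(),
                            C, X, Y, Z, N, Cout, k, s, p, OX, OY, OZ);
  y.attr("dim") = IntegerVector::create(Cout, OX, OY, OZ, N);
  return y;
}

template <typename T>
static void conv3d_bwd_core(const double* x, const double* dy,
                            const double* Wp,
                            double* dxp, double* dWp, double* dbp,
                            bool want_dx, bool want_dw,
                            int C, int X, int Y, int Z, int N, int Cout,
                            const int* k, const int* s, const int* p,
                            int OX, int OY, int OZ) {
  R_xlen_t K = (R_xlen_t)C * k[0] * k[1] * k[2];
  R_xlen_t L = (R_xlen_t)OX * OY * OZ;
  R_xlen_t in_stride = (R_xlen_t)C * X * Y * Z;
  R_xlen_t out_stride = (R_xlen_t)Cout * L;
  arma::Mat<T> W(Cout, K);
  std::copy(Wp, Wp + (R_xlen_t)Cout * K, W.memptr());
  arma::Mat<T> dW(Cout, K, arma::fill::zeros);
  arma::Col<T> db(Cout, arma::fill::zeros);
  arma::Mat<T> cols(K, L);
  arma::Mat<T> dym(Cout, L);
  arma::Col<T> buf(std::max(in_stride, (R_xlen_t)1));
  im2col_zero_pad(p, cols);
  for (int n = 0; n < N; ++n) {
    std::copy(dy + n * out_stride, dy + (n + 1) * out_stride, dym.memptr());
    if (want_dw) {
      std::copy(x + n * in_stride, x + (n + 1) * in_stride, buf.memptr());
      im2col(buf.memptr(), C, X, Y, Z, k, s, p, OX, OY, OZ, cols);
      dW += dym * cols.t();
      db += arma::sum(dym, 1);
    }
    if (want_dx) {
      arma::Mat<T> dcols = W.t() * dym;
      buf.zeros();
      col2im_add(dcols, buf.memptr(), C, X, Y, Z, k, s, p, OX, OY, OZ);
      std::copy(buf.memptr(), buf.memptr() + in_stride, dxp + n * in_stride);
    }
  }
  if (want_dw) {
    std::copy(dW.memptr(), dW.memptr() + (R_xlen_t)Cout * K, dWp);
    std::copy(db.memptr(), db.memptr() + Cout, dbp);
  }
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xdim,
                    NumericMatrix Wm, NumericVector dy,
                    IntegerVector kk, IntegerVector ss, IntegerVector pp,
                    bool want_dx, bool want_dw, bool single = false) {
  int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3], N = xdim[4];
  int k[3] = {kk[0], kk[1], kk[2]};
  int s[3] = {ss[0], ss[1], ss[2]};
  int p[3] = {pp[0], pp[1], pp[2]};
  int Cout = Wm.nrow();
  int OX = (X + 2 * p[0] - k[0]) / s[0] + 1;
  int OY = (Y + 2 * p[1] - k[1]) / s[1] + 1;
  int OZ = (Z + 2 * p[2] - k[2]) / s[2] + 1;
  R_xlen_t K = (R_xlen_t)C * k[0] * k[1] * k[2];
  R_xlen_t in_stride = (R_xlen_t)C * X * Y * Z;
  NumericVector dx(want_dx ? in_stride * N : 0);
  NumericVector dW(want_dw ? (R_xlen_t)Cout * K : 0);
  NumericVector db(want_dw ? Cout : 0);
  if (single)
    conv3d_bwd_core<float>(x.begin(), dy.begin(), Wm.begin(),
                           dx.begin(), dW.begin(), db.begin(),
                           want_dx, want_dw,
                           C, X, Y, Z, N, Cout, k, s, p, OX, OY, OZ);
  else
    conv3d_bwd_core<double>(x.begin(), dy.begin(), Wm.begin(),
                            dx.begin(), dW.begin(), db.begin(),
                            want_dx, want_dw,
                            C, X, Y, Z, N, Cout, k, s, p, OX, OY, OZ);
  List out = List::create(Named("dx") = R_NilValue,
                          Named("dW") = R_NilValue,
                          Named("db") = R_NilValue);
  if (want_dx) {
    dx.attr("dim") = xdim;
    out["dx"] = dx;
  }
  if (want_dw) {
    dW.attr("dim") = IntegerVector::create(Cout, C, k[0], k[1], k[2]);
    out["dW"] = dW;
    out["db"] = db;
  }
  return out;
}

// Transposed convolution.  W has dim c(Cin, Cout, k0, k1, k2); output spatial
// size o = (i - 1) * s - 2p + k.  Inputs are tiny (the latent lift), so plain
// loops suffice.
// [[Rcpp::export]]
NumericVector cpp_tconv3d_fwd(NumericVector x, IntegerVector xdim,
                              NumericVector Wv, IntegerVector wdim,
                              NumericVector b,
                              IntegerVector ss, IntegerVector pp) {
  int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3], N = xdim[4];
  int Cin = wdim[0], Cout = wdim[1];
  int k[3] = {wdim[2], wdim[3], wdim[4]};
  int s[3] = {ss[0], ss[1], ss[2]};
  int p[3] = {pp[0], pp[1], pp[2]};
  if (Cin != C) stop("tconv3d: channel mismatch");
  int OX = (X - 1) * s[0] - 2 * p[0] + k[0];
  int OY = (Y - 1) * s[1] - 2 * p[1] + k[1];
  int OZ = (Z - 1) * s[2] - 2 * p[2] + k[2];
  if (OX < 1 || OY < 1 || OZ < 1) stop("tconv3d: non-positive output size");
  R_xlen_t in_stride = (R_xlen_t)C * X * Y * Z;
  R_xlen_t out_stride = (R_xlen_t)Cout * OX * OY * OZ;
  NumericVector y(out_stride * N);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + n * in_stride;
    double* ys = y.begin() + n * out_stride;
    for (int co = 0; co < Cout; ++co)
      for (R_xlen_t l = 0; l < (R_xlen_t)OX * OY * OZ; ++l)
        ys[co + Cout * l] = b[co];
    for (int z = 0; z < Z; ++z)
      for (int yy = 0; yy < Y; ++yy)
        for (int xx = 0; xx < X; ++xx)
          for (int ci = 0; ci < C; ++ci) {
            double v = xs[idx4(ci, xx, yy, z, C, X, Y)];
            if (v == 0.0) continue;
            for (int c2 = 0; c2 < k[2]; ++c2) {
              int oz = z * s[2] - p[2] + c2;
              if (oz < 0 || oz >= OZ) continue;
              for (int c1 = 0; c1 < k[1]; ++c1) {
                int oy = yy * s[1] - p[1] + c1;
                if (oy < 0 || oy >= OY) continue;
                for (int c0 = 0; c0 < k[0]; ++c0) {
                  int ox = xx * s[0] - p[0] + c0;
                  if (ox < 0 || ox >= OX) continue;
                  for (int co = 0; co < Cout; ++co) {
                    double w = Wv[ci + (R_xlen_t)Cin * (co + (R_xlen_t)Cout *
                               (c0 + (R_xlen_t)k[0] * (c1 + (R_xlen_t)k[1] * c2)))];
                    ys[idx4(co, ox, oy, oz, Cout, OX, OY)] += v * w;
                  }
                }
              }
            }
          }
  }
  y.attr("dim") = IntegerVector::create(Cout, OX, OY, OZ, N);
  return y;
}

// [[Rcpp::export]]
List cpp_tconv3d_bwd(NumericVector x, IntegerVector xdim,
                     NumericVector Wv, IntegerVector wdim,
                     NumericVector dy,
                     IntegerVector ss, IntegerVector pp,
                     bool want_dx, bool want_dw) {
  int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3], N = xdim[4];
  int Cin = wdim[0], Cout = wdim[1];
  int k[3] = {wdim[2], wdim[3], wdim[4]};
  int s[3] = {ss[0], ss[1], ss[2]};
  int p[3] = {pp[0], pp[1], pp[2]};
  int OX = (X - 1) * s[0] - 2 * p[0] + k[0];
  int OY = (Y - 1) * s[1] - 2 * p[1] + k[1];
  int OZ = (Z - 1) * s[2] - 2 * p[2] + k[2];
  R_xlen_t in_stride = (R_xlen_t)C * X * Y * Z;
  R_xlen_t out_stride = (R_xlen_t)Cout * OX * OY * OZ;
  NumericVector dx(want_dx ? in_stride * N : 0);
  NumericVector dW(want_dw ? Wv.size() : 0);
  NumericVector db(want_dw ? Cout : 0);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + n * in_stride;
    const double* dys = dy.begin() + n * out_stride;
    double* dxs = want_dx ? dx.begin() + n * in_stride : nullptr;
    if (want_dw)
      for (int co = 0; co < Cout; ++co)
        for (R_xlen_t l = 0; l < (R_xlen_t)OX * OY * OZ; ++l)
          db[co] += dys[co + Cout * l];
    for (int z = 0; z < Z; ++z)
      for (int yy = 0; yy < Y; ++yy)
        for (int xx = 0; xx < X; ++xx)
          for (int ci = 0; ci < C; ++ci) {
            double xv = xs[idx4(ci, xx, yy, z, C, X, Y)];
            double acc = 0.0;
            for (int c2 = 0; c2 < k[2]; ++c2) {
              int oz = z * s[2] - p[2] + c2;
              if (oz < 0 || oz >= OZ) continue;
              for (int c1 = 0; c1 < k[1]; ++c1) {
                int oy = yy * s[1] - p[1] + c1;
                if (oy < 0 || oy >= OY) continue;
                for (int c0 = 0; c0 < k[0]; ++c0) {
                  int ox = xx * s[0] - p[0] + c0;
                  if (ox < 0 || ox >= OX) continue;
                  for (int co = 0; co < Cout; ++co) {
                    R_xlen_t wi = ci + (R_xlen_t)Cin * (co + (R_xlen_t)Cout *
                               (c0 + (R_xlen_t)k[0] * (c1 + (R_xlen_t)k[1] * c2)));
                    double g = dys[idx4(co, ox, oy, oz, Cout, OX, OY)];
                    if (want_dx) acc += Wv[wi] * g;
                    if (want_dw) dW[wi] += xv * g;
                  }
                }
              }
            }
            if (want_dx) dxs[idx4(ci, xx, yy, z, C, X, Y)] = acc;
          }
  }
  List out = List::create(Named("dx") = R_NilValue,
                          Named("dW") = R_NilValue,
                          Named("db") = R_NilValue);
  if (want_dx) {
    dx.attr("dim") = xdim;
    out["dx"] = dx;
  }
  if (want_dw) {
    dW.attr("dim") = wdim;
    out["dW"] = dW;
    out["db"] = db;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nn_fwd(NumericVector x, IntegerVector xdim,
                                  IntegerVector sc) {
  int C = xdim[0], X = xdim[1], Y = xdim[2], Z = xdim[3], N = xdim[4];
  int OX = X * sc[0], OY = Y * sc[1], OZ = Z * sc[2];
  R_xlen_t in_stride = (R_xlen_t)C * X * Y * Z;
  R_xlen_t out_stride = (R_xlen_t)C * OX * OY * OZ;
  NumericVector y(out_stride * N);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + n * in_stride;
    double* ys = y.begin() + n * out_stride;
    for (int oz = 0; oz < OZ; ++oz)
      for (int oy = 0; oy < OY; ++oy)
        for (int ox = 0; ox < OX; ++ox) {
          double* dst = ys + idx4(0, ox, oy, oz, C, OX, OY);
          const double* src = xs + idx4(0, ox / sc[0], oy / sc[1], oz / sc[2], C, X, Y);
          for (int c = 0; c < C; ++c) dst[c] = src[c];
        }
  }
  y.attr("dim") = IntegerVector::create(C, OX, OY, OZ, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nn_bwd(NumericVector dy, IntegerVector ydim,
                                  IntegerVector sc) {
  int C = ydim[0], OX = ydim[1], OY = ydim[2], OZ = ydim[3], N = ydim[4];
  int X = OX / sc[0], Y = OY / sc[1], Z = OZ / sc[2];
  R_xlen_t in_stride = (R_xlen_t)C * X * Y * Z;
  R_xlen_t out_stride = (R_xlen_t)C * OX * OY * OZ;
  NumericVector dx(in_stride * N);
  for (int n = 0; n < N; ++n) {
    const double* dys = dy.begin() + n * out_stride;
    double* dxs = dx.begin() + n * in_stride;
    for (int oz = 0; oz < OZ; ++oz)
      for (int oy = 0; oy < OY; ++oy)
        for (int ox = 0; ox < OX; ++ox) {
          const double* src = dys + idx4(0, ox, oy, oz, C, OX, OY);
          double* dst = dxs + idx4(0, ox / sc[0], oy / sc[1], oz / sc[2], C, X, Y);
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
  }
  dx.attr("dim") = IntegerVector::create(C, X, Y, Z, N);
  return dx;
}

// Trilinear interpolation of a [C, X, Y, Z] volume at continuous 0-based
// voxel coordinates (one row per query point).  mode 0: clamp to the edge,
// mode 1: zero outside the grid.
// [[Rcpp::export]]
NumericMatrix cpp_trilinear_sample(NumericVector vol, IntegerVector vdim,
                                   NumericMatrix coords, int mode) {
  int C = vdim[0], X = vdim[1], Y = vdim[2], Z = vdim[3];
  int n = coords.nrow();
  NumericMatrix out(C, n);
  for (int i = 0; i < n; ++i) {
    double cx = coords(i, 0), cy = coords(i, 1), cz = coords(i, 2);
    if (mode == 1 &&
        (cx < -1 || cx > X || cy < -1 || cy > Y || cz < -1 || cz > Z)) {
      continue;  // fully outside: zeros
    }
    if (mode == 0) {
      cx = std::min(std::max(cx, 0.0), (double)(X - 1));
      cy = std::min(std::max(cy, 0.0), (double)(Y - 1));
      cz = std::min(std::max(cz, 0.0), (double)(Z - 1));
    }
    int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
    double fx = cx - x0, fy = cy - y0, fz = cz - z0;
    for (int dz = 0; dz < 2; ++dz) {
      int z = z0 + dz;
      double wz = dz ? fz : 1 - fz;
      if (wz == 0) continue;
      for (int dyy = 0; dyy < 2; ++dyy) {
        int y = y0 + dyy;
        double wy = dyy ? fy : 1 - fy;
        if (wy == 0) continue;
        for (int dxx = 0; dxx < 2; ++dxx) {
          int x = x0 + dxx;
          double wx = dxx ? fx : 1 - fx;
          if (wx == 0) continue;
          int xc = x, yc = y, zc = z;
          if (mode == 0) {
            xc = std::min(std::max(xc, 0), X - 1);
            yc = std::min(std::max(yc, 0), Y - 1);
            zc = std::min(std::max(zc, 0), Z - 1);
          } else if (xc < 0 || xc >= X || yc < 0 || yc >= Y ||
                     zc < 0 || zc >= Z) {
            continue;
          }
          double w = wx * wy * wz;
          const double* src = vol.begin() + idx4(0, xc, yc, zc, C, X, Y);
          for (int c = 0; c < C; ++c) out(c, i) += w * src[c];
        }
      }
    }
  }
  return out;
}

// float tanh via the degree-13/6 rational minimax approximation used by the
// mainstream deep-learning runtimes (float-accurate, auto-vectorizable)
static inline float fast_tanhf(float x) {
  const float clamp = 7.90531110763549805f;
  x = x > clamp ? clamp : (x < -clamp ? -clamp : x);
  const float x2 = x * x;
  float alpha = -2.76076847742355e-16f;
  alpha = alpha * x2 + 2.00018790482477e-13f;
  alpha = alpha * x2 + -8.60467152213735e-11f;
  alpha = alpha * x2 + 5.12229709037114e-08f;
  alpha = alpha * x2 + 1.48572235717979e-05f;
  alpha = alpha * x2 + 6.37261928875436e-04f;
  alpha = alpha * x2 + 4.89352455891786e-03f;
  float beta = 1.19825839466702e-06f;
  beta = beta * x2 + 1.18534705686654e-04f;
  beta = beta * x2 + 2.26843463243900e-03f;
  beta = beta * x2 + 4.89352518554385e-03f;
  return (x * alpha) / beta;
}

// Fused activations: kind 0 = identity, 1 = relu, 2 = leaky relu, 3 = tanh.
// `single` evaluates tanh in float precision (the engine's single-precision
// training mode).
// [[Rcpp::export]]
NumericVector cpp_act_fwd(NumericVector x, int kind, double slope,
                          bool single = false) {
  R_xlen_t n = x.size();
  NumericVector y(n);
  const double* xp = x.begin();
  double* yp = y.begin();
  switch (kind) {
  case 0: std::memcpy(yp, xp, n * sizeof(double)); break;
  case 1: for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0; break;
  case 2: for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : slope * xp[i]; break;
  case 3:
    if (single)
      for (R_xlen_t i = 0; i < n; ++i) yp[i] = fast_tanhf((float)xp[i]);
    else
      for (R_xlen_t i = 0; i < n; ++i) yp[i] = std::tanh(xp[i]);
    break;
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// backward uses the pre-activation x for (leaky) relu and the output y for tanh
// [[Rcpp::export]]
NumericVector cpp_act_bwd(NumericVector ref, NumericVector dy, int kind,
                          double slope) {
  R_xlen_t n = dy.size();
  NumericVector dx(n);
  const double* rp = ref.begin();
  const double* dp = dy.begin();
  double* op = dx.begin();
  switch (kind) {
  case 0: std::memcpy(op, dp, n * sizeof(double)); break;
  case 1: for (R_xlen_t i = 0; i < n; ++i) op[i] = rp[i] > 0 ? dp[i] : 0.0; break;
  case 2: for (R_xlen_t i = 0; i < n; ++i) op[i] = rp[i] > 0 ? dp[i] : slope * dp[i]; break;
  case 3: for (R_xlen_t i = 0; i < n; ++i) op[i] = dp[i] * (1.0 - rp[i] * rp[i]); break;
  }
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// per-sample convex combination: out[, n] = w[n] * a[, n] + (1 - w[n]) * b[, n]
// [[Rcpp::export]]
NumericVector cpp_mix_batch(NumericVector a, NumericVector b,
                            NumericVector w) {
  R_xlen_t n = w.size();
  R_xlen_t m = a.size() / n;
  NumericVector out(a.size());
  for (R_xlen_t j = 0; j < n; ++j) {
    double wj = w[j], vj = 1.0 - wj;
    const double* ap = a.begin() + j * m;
    const double* bp = b.begin() + j * m;
    double* op = out.begin() + j * m;
    for (R_xlen_t i = 0; i < m; ++i) op[i] = wj * ap[i] + vj * bp[i];
  }
  out.attr("dim") = a.attr("dim");
  return out;
}

// per-sample sums of absolute differences (the batched L1 norms)
// [[Rcpp::export]]
NumericVector cpp_l1_cols(NumericVector a, NumericVector b, int n) {
  R_xlen_t m = a.size() / n;
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    const double* ap = a.begin() + (R_xlen_t)j * m;
    const double* bp = b.begin() + (R_xlen_t)j * m;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < m; ++i) acc += std::fabs(ap[i] - bp[i]);
    out[j] = acc;
  }
  return out;
}

// dy + coef * sign(a - b), the subgradient of the scaled L1 term
// [[Rcpp::export]]
NumericVector cpp_add_sign(NumericVector dy, NumericVector a,
                           NumericVector b, double coef) {
  NumericVector out(dy.size());
  for (R_xlen_t i = 0; i < dy.size(); ++i) {
    double d = a[i] - b[i];
    out[i] = dy[i] + (d > 0 ? coef : (d < 0 ? -coef : 0.0));
  }
  out.attr("dim") = dy.attr("dim");
  return out;
}

// per-sample L2 norms over the flattened non-batch dimensions
// [[Rcpp::export]]
NumericVector cpp_col_norms(NumericVector x, int n) {
  R_xlen_t m = x.size() / n;
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    const double* p = x.begin() + (R_xlen_t)j * m;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < m; ++i) acc += p[i] * p[i];
    out[j] = std::sqrt(acc);
  }
  return out;
}

// scale each sample slice by its own coefficient
// [[Rcpp::export]]
NumericVector cpp_scale_cols(NumericVector x, NumericVector coef) {
  R_xlen_t n = coef.size();
  R_xlen_t m = x.size() / n;
  NumericVector out(x.size());
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* p = x.begin() + j * m;
    double* o = out.begin() + j * m;
    double c = coef[j];
    for (R_xlen_t i = 0; i < m; ++i) o[i] = c * p[i];
  }
  out.attr("dim") = x.attr("dim");
  return out;
}

// x + a * y, preserving dim
// [[Rcpp::export]]
NumericVector cpp_axpy(NumericVector x, NumericVector y, double a) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = x[i] + a * y[i];
  out.attr("dim") = x.attr("dim");
  return out;
}

// concatenate two equally shaped batches along the batch dimension
// [[Rcpp::export]]
NumericVector cpp_cat_batch(NumericVector a, NumericVector b) {
  NumericVector out(a.size() + b.size());
  std::copy(a.begin(), a.end(), out.begin());
  std::copy(b.begin(), b.end(), out.begin() + a.size());
  return out;
}
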