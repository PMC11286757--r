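// Hot tensor kernels for the network: 2-D (dilated) convolution via
// im2col + GEMM, 2x2 max pooling, and bilinear resampling, each with its
// backward pass. All volumes are R arrays in (H, W, C, N) layout
// (column-major, H fastest), kernels in (kh, kw, Cin, Cout) layout --
// which flattens to a (kh*kw*Cin) x Cout matrix with no copy.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline Rcpp::NumericVector num4(int a, int b, int c, int d) {
  Rcpp::NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = Rcpp::IntegerVector::create(a, b, c, d);
  return v;
}

static inline Rcpp::IntegerVector int4(int a, int b, int c, int d) {
  Rcpp::IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = Rcpp::IntegerVector::create(a, b, c, d);
  return v;
}


static inline int clampi(int v, int hi) {
  return v < 0 ? 0 : (v > hi ? hi : v);
}

// Same-size padding uses edge replication (clamp-to-border): stained-smear
// images have no natural zero border, and zero padding would manufacture
// strong spurious edge responses along the canvas boundary.
static inline void im2col(const double* x, int H, int W, int C,
                          int kh, int kw, int dil, int ph, int pw,
                          arma::mat& K) {
  // K is (kh*kw*C) x (H*W); output position (i,j) -> column i + H*j
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        int r = di + kh * (dj + kw * c);
        int oi = di * dil - ph;   // row offset into source
        int oj = dj * dil - pw;
        for (int j = 0; j < W; ++j) {
          int sj = clampi(j + oj, W - 1);
          const double* col = xc + (size_t)sj * H;
          double* dst = K.colptr(j * H) + r;
          for (int i = 0; i < H; ++i) {
            *dst = col[clampi(i + oi, H - 1)];
            dst += K.n_rows;
          }
        }
      }
    }
  }
}

static inline void col2im_add(const arma::mat& K, int H, int W, int C,
                              int kh, int kw, int dil, int ph, int pw,
                              double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        int r = di + kh * (dj + kw * c);
        int oi = di * dil - ph;
        int oj = dj * dil - pw;
        for (int j = 0; j < W; ++j) {
          int sj = clampi(j + oj, W - 1);
          double* col = xc + (size_t)sj * H;
          const double* src = K.memptr() + (size_t)r +
            (size_t)j * H * K.n_rows;
          for (int i = 0; i < H; ++i) {
            col[clampi(i + oi, H - 1)] += *src;
            src += K.n_rows;
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels but kernel expects %d", C, Cin);
  int ph = dilation * (kh - 1) / 2, pw = dilation * (kw - 1) / 2;
  int R = kh * kw * C, HW = H * W;

  NumericVector out = num4(H, W, Cout, N);
  arma::mat WT(const_cast<double*>(w.begin()), R, Cout, false, true);
  arma::mat K(R, HW);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, dilation, ph, pw, K);
    arma::mat Yt(out.begin() + (size_t)n * HW * Cout, HW, Cout, false, true);
    Yt = K.t() * WT;
    Yt.each_row() += bv;
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int ph = dilation * (kh - 1) / 2, pw = dilation * (kw - 1) / 2;
  int R = kh * kw * C, HW = H * W;

  NumericVector dx = num4(H, W, C, N);
  NumericVector dw = num4(kh, kw, C, Cout);
  NumericVector db(Cout);

  arma::mat WT(const_cast<double*>(w.begin()), R, Cout, false, true);
  arma::mat dWT(dw.begin(), R, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  arma::mat K(R, HW);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, dilation, ph, pw, K);
    arma::mat dYt(const_cast<double*>(dy.begin()) + (size_t)n * HW * Cout,
                  HW, Cout, false, true);
    dWT += K * dYt;
    dbv += arma::sum(dYt, 0);
    arma::mat dK = WT * dYt.t();   // (R, HW)
    col2im_add(dK, H, W, C, kh, kw, dilation, ph, pw,
               dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int H2 = H / 2, W2 = W / 2;
  NumericVector y = num4(H2, W2, C, N);
  IntegerVector idx = int4(H2, W2, C, N);  // 0-based linear index into x
  size_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      size_t base = ((size_t)n * C + c) * H * W;
      for (int j = 0; j < W2; ++j) {
        for (int i = 0; i < H2; ++i) {
          int i0 = 2 * i, j0 = 2 * j;
          double best = xc[i0 + (size_t)j0 * H];
          size_t bidx = i0 + (size_t)j0 * H;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              size_t k = (i0 + di) + (size_t)(j0 + dj) * H;
              if (xc[k] > best) { best = xc[k]; bidx = k; }
            }
          y[q] = best;
          idx[q] = (int)(base + bidx);
          ++q;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(IntegerVector idx, NumericVector dy,
                           IntegerVector xdim) {
  size_t total = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx((R_xlen_t)total);
  dx.attr("dim") = xdim;
  for (R_xlen_t q = 0; q < dy.size(); ++q) dx[idx[q]] += dy[q];
  return dx;
}

static inline void lin_coef(int outL, int inL, int d, int& lo, int& hi,
                            double& wlo) {
  double s = ((double)d + 0.5) * inL / outL - 0.5;
  if (s < 0) s = 0;
  if (s > inL - 1) s = inL - 1;
  lo = (int)std::floor(s);
  hi = std::min(lo + 1, inL - 1);
  wlo = 1.0 - (s - lo);
}

// [[Rcpp::export(name = ".bilinear_fwd")]]
NumericVector bilinear_fwd(NumericVector x, int outH, int outW) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y = num4(outH, outW, C, N);
  std::vector<int> ilo(outH), ihi(outH), jlo(outW), jhi(outW);
  std::vector<double> iw(outH), jw(outW);
  for (int i = 0; i < outH; ++i) lin_coef(outH, H, i, ilo[i], ihi[i], iw[i]);
  for (int j = 0; j < outW; ++j) lin_coef(outW, W, j, jlo[j], jhi[j], jw[j]);
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      for (int j = 0; j < outW; ++j)
        for (int i = 0; i < outH; ++i) {
          double a = iw[i], bta = jw[j];
          y[q++] =
            a * bta * xc[ilo[i] + (size_t)jlo[j] * H] +
            (1 - a) * bta * xc[ihi[i] + (size_t)jlo[j] * H] +
            a * (1 - bta) * xc[ilo[i] + (size_t)jhi[j] * H] +
            (1 - a) * (1 - bta) * xc[ihi[i] + (size_t)jhi[j] * H];
        }
    }
  return y;
}

// [[Rcpp::export(name = ".bilinear_bwd")]]
NumericVector bilinear_bwd(NumericVector dy, int inH, int inW) {
  IntegerVector yd = dy.attr("dim");
  int outH = yd[0], outW = yd[1], C = yd[2], N = yd[3];
  NumericVector dx = num4(inH, inW, C, N);
  std::vector<int> ilo(outH), ihi(outH), jlo(outW), jhi(outW);
  std::vector<double> iw(outH), jw(outW);
  for (int i = 0; i < outH; ++i) lin_coef(outH, inH, i, ilo[i], ihi[i], iw[i]);
  for (int j = 0; j < outW; ++j) lin_coef(outW, inW, j, jlo[j], jhi[j], jw[j]);
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + ((size_t)n * C + c) * inH * inW;
      for (int j = 0; j < outW; ++j)
        for (int i = 0; i < outH; ++i) {
          double g = dy[q++], a = iw[i], bta = jw[j];
          xc[ilo[i] + (size_t)jlo[j] * inH] += a * bta * g;
          xc[ihi[i] + (size_t)jlo[j] * inH] += (1 - a) * bta * g;
          xc[ilo[i] + (size_t)jhi[j] * inH] += a * (1 - bta) * g;
          xc[ihi[i] + (size_t)jhi[j] * inH] += (1 - a) * (1 - bta) * g;
        }
    }
  return dx;
}
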