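// Low-level array kernels for the network and image pipeline.
// All image batches use the layout [H, W, C, N] (column-major, H fastest),
// matching R arrays with dim = c(H, W, C, N). Weights are [kh, kw, Cin, Cout].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::cube as_cube_view(const NumericVector& x, int H, int W, int CN) {
  // zero-copy view of an R array as H x W x (C*N)
  return arma::cube(const_cast<double*>(x.begin()), H, W, CN, false, true);
}

// Build the im2col matrix for samples: rows indexed (ky, kx, ci) with ky
// fastest, columns indexed output pixel (ho fastest). Zero padding.
// Columns are written contiguously, and the matrix is single precision:
// the GEMMs run in float (ample for network training) while all R-facing
// arrays stay double.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::fmat& K, std::size_t col0) {
  const int KK = kh * kw;
  for (int wo = 0; wo < Wo; ++wo) {
    const int wb = wo * stride - pad;
    for (int ho = 0; ho < Ho; ++ho) {
      float* Kc = K.colptr(col0 + (std::size_t)wo * Ho + ho);
      const int hb = ho * stride - pad;
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = x + (std::size_t)ci * H * W;
        for (int kx = 0; kx < kw; ++kx) {
          const int wi = wb + kx;
          float* Kr = Kc + ci * KK + kx * kh;
          if (wi < 0 || wi >= W) {
            for (int ky = 0; ky < kh; ++ky) Kr[ky] = 0.0f;
            continue;
          }
          const double* xcol = xc + (std::size_t)wi * H;
          for (int ky = 0; ky < kh; ++ky) {
            const int hi = hb + ky;
            Kr[ky] = (hi >= 0 && hi < H) ? (float)xcol[hi] : 0.0f;
          }
        }
      }
    }
  }
}

static void col2im(const arma::fmat& K, std::size_t col0, double* gx,
                   int H, int W, int C,
                   int kh, int kw, int stride, int pad, int Ho, int Wo) {
  const int KK = kh * kw;
  for (int wo = 0; wo < Wo; ++wo) {
    const int wb = wo * stride - pad;
    for (int ho = 0; ho < Ho; ++ho) {
      const float* Kc = K.colptr(col0 + (std::size_t)wo * Ho + ho);
      const int hb = ho * stride - pad;
      for (int ci = 0; ci < C; ++ci) {
        double* xc = gx + (std::size_t)ci * H * W;
        for (int kx = 0; kx < kw; ++kx) {
          const int wi = wb + kx;
          if (wi < 0 || wi >= W) continue;
          const float* Kr = Kc + ci * KK + kx * kh;
          double* xcol = xc + (std::size_t)wi * H;
          for (int ky = 0; ky < kh; ++ky) {
            const int hi = hb + ky;
            if (hi >= 0 && hi < H) xcol[hi] += Kr[ky];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch in conv2d");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int KR = kh * kw * Cin;
  const std::size_t P = (std::size_t)Ho * Wo;

  // weight as KR x Cout, rows in im2col order
  arma::fmat Wm(KR, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kx = 0; kx < kw; ++kx)
        for (int ky = 0; ky < kh; ++ky)
          Wm(ci * kh * kw + kx * kh + ky, co) =
            (float)w[((std::size_t)co * Cin + ci) * kh * kw + kx * kh + ky];

  NumericVector y(P * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  // one im2col matrix for the whole batch, one GEMM
  arma::fmat K(KR, P * N);
  for (int n = 0; n < N; ++n)
    im2col(x.begin() + (std::size_t)n * H * W * C, H, W, C, kh, kw, stride,
           pad, Ho, Wo, K, (std::size_t)n * P);
  arma::fmat Yt = K.t() * Wm;  // (P*N) x Cout
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const float* src = Yt.colptr(co) + (std::size_t)n * P;
      double* dst = y.begin() + ((std::size_t)n * Cout + co) * P;
      const double bb = b[co];
      for (std::size_t p = 0; p < P; ++p) dst[p] = (double)src[p] + bb;
    }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, bool need_gx, bool need_gw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  const int KR = kh * kw * Cin;
  const std::size_t P = (std::size_t)Ho * Wo;

  arma::fmat Wm(KR, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kx = 0; kx < kw; ++kx)
        for (int ky = 0; ky < kh; ++ky)
          Wm(ci * kh * kw + kx * kh + ky, co) =
            (float)w[((std::size_t)co * Cin + ci) * kh * kw + kx * kh + ky];

  // gy reshaped with sample-major rows: (P*N) x Cout
  arma::fmat Gy(P * N, Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = gy.begin() + ((std::size_t)n * Cout + co) * P;
      float* dst = Gy.colptr(co) + (std::size_t)n * P;
      for (std::size_t p = 0; p < P; ++p) dst[p] = (float)src[p];
    }

  arma::fmat Gw;
  arma::frowvec Gb;
  if (need_gw) {
    arma::fmat K(KR, P * N);
    for (int n = 0; n < N; ++n)
      im2col(x.begin() + (std::size_t)n * H * W * C, H, W, C, kh, kw,
             stride, pad, Ho, Wo, K, (std::size_t)n * P);
    Gw = K * Gy;
    Gb = arma::sum(Gy, 0);
  } else {
    Gw.zeros(KR, Cout);
    Gb.zeros(Cout);
  }
  NumericVector gx(need_gx ? x.size() : 0);
  if (need_gx) {
    gx.attr("dim") = xd;
    arma::fmat Gk = Wm * Gy.t();                // KR x (P*N)
    for (int n = 0; n < N; ++n)
      col2im(Gk, (std::size_t)n * P, gx.begin() + (std::size_t)n * H * W * C,
             H, W, C, kh, kw, stride, pad, Ho, Wo);
  }

  NumericVector gwv((std::size_t)kh * kw * Cin * Cout);
  gwv.attr("dim") = wd;
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kx = 0; kx < kw; ++kx)
        for (int ky = 0; ky < kh; ++ky)
          gwv[((std::size_t)co * Cin + ci) * kh * kw + kx * kh + ky] =
            Gw(ci * kh * kw + kx * kh + ky, co);

  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(Gb.begin(), Gb.end()));
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_fwd(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] >= 0 ? x[i] : slope * x[i];
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_bwd(NumericVector x, NumericVector g, double slope) {
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    gx[i] = x[i] >= 0 ? g[i] : slope * g[i];
  return gx;
}

// Separable correlation with an odd symmetric kernel, "valid" output region.
// [[Rcpp::export]]
NumericVector cpp_sepconv_valid(NumericVector x, NumericVector k) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], CN = xd[2] * xd[3];
  const int L = k.size();
  const int Ho = H - L + 1, Wo = W - L + 1;
  if (Ho < 1 || Wo < 1) stop("image too small for window");
  NumericVector y((std::size_t)Ho * Wo * CN);
  y.attr("dim") = IntegerVector::create(Ho, Wo, xd[2], xd[3]);
  arma::mat tmp(Ho, W);
  for (int s = 0; s < CN; ++s) {
    const double* xs = x.begin() + (std::size_t)s * H * W;
    // vertical pass
    for (int wI = 0; wI < W; ++wI) {
      const double* col = xs + (std::size_t)wI * H;
      for (int ho = 0; ho < Ho; ++ho) {
        double acc = 0.0;
        for (int t = 0; t < L; ++t) acc += k[t] * col[ho + t];
        tmp(ho, wI) = acc;
      }
    }
    // horizontal pass
    double* ys = y.begin() + (std::size_t)s * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double acc = 0.0;
        for (int t = 0; t < L; ++t) acc += k[t] * tmp(ho, wo + t);
        ys[(std::size_t)wo * Ho + ho] = acc;
      }
    }
  }
  return y;
}

// Full separable convolution (adjoint of cpp_sepconv_valid for symmetric k):
// output is (Hg + L - 1) x (Wg + L - 1).
// [[Rcpp::export]]
NumericVector cpp_sepconv_full(NumericVector g, NumericVector k) {
  IntegerVector gd = g.attr("dim");
  const int Hg = gd[0], Wg = gd[1], CN = gd[2] * gd[3];
  const int L = k.size();
  const int Ho = Hg + L - 1, Wo = Wg + L - 1;
  NumericVector y((std::size_t)Ho * Wo * CN);
  y.attr("dim") = IntegerVector::create(Ho, Wo, gd[2], gd[3]);
  arma::mat tmp(Ho, Wg);
  for (int s = 0; s < CN; ++s) {
    const double* gs = g.begin() + (std::size_t)s * Hg * Wg;
    tmp.zeros();
    for (int wI = 0; wI < Wg; ++wI) {
      const double* col = gs + (std::size_t)wI * Hg;
      for (int hg = 0; hg < Hg; ++hg) {
        const double v = col[hg];
        if (v == 0.0) continue;
        for (int t = 0; t < L; ++t) tmp(hg + t, wI) += k[t] * v;
      }
    }
    double* ys = y.begin() + (std::size_t)s * Ho * Wo;
    std::fill(ys, ys + (std::size_t)Ho * Wo, 0.0);
    for (int wg = 0; wg < Wg; ++wg) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double v = tmp(ho, wg);
        if (v == 0.0) continue;
        for (int t = 0; t < L; ++t)
          ys[(std::size_t)(wg + t) * Ho + ho] += k[t] * v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], CN = xd[2] * xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((std::size_t)Ho * Wo * CN);
  y.attr("dim") = IntegerVector::create(Ho, Wo, xd[2], xd[3]);
  for (int s = 0; s < CN; ++s) {
    const double* xs = x.begin() + (std::size_t)s * H * W;
    double* ys = y.begin() + (std::size_t)s * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        ys[(std::size_t)wo * Ho + ho] = 0.25 *
          (xs[(std::size_t)(2 * wo) * H + 2 * ho] +
           xs[(std::size_t)(2 * wo) * H + 2 * ho + 1] +
           xs[(std::size_t)(2 * wo + 1) * H + 2 * ho] +
           xs[(std::size_t)(2 * wo + 1) * H + 2 * ho + 1]);
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bwd(NumericVector g, int H, int W) {
  IntegerVector gd = g.attr("dim");
  const int Ho = gd[0], Wo = gd[1], CN = gd[2] * gd[3];
  NumericVector y((std::size_t)H * W * CN);
  y.attr("dim") = IntegerVector::create(H, W, gd[2], gd[3]);
  for (int s = 0; s < CN; ++s) {
    const double* gs = g.begin() + (std::size_t)s * Ho * Wo;
    double* ys = y.begin() + (std::size_t)s * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double v = 0.25 * gs[(std::size_t)wo * Ho + ho];
        ys[(std::size_t)(2 * wo) * H + 2 * ho] += v;
        ys[(std::size_t)(2 * wo) * H + 2 * ho + 1] += v;
        ys[(std::size_t)(2 * wo + 1) * H + 2 * ho] += v;
        ys[(std::size_t)(2 * wo + 1) * H + 2 * ho + 1] += v;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], CN = xd[2] * xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((std::size_t)Ho * Wo * CN);
  y.attr("dim") = IntegerVector::create(Ho, Wo, xd[2], xd[3]);
  for (int s = 0; s < CN; ++s) {
    const double* xs = x.begin() + (std::size_t)s * H * W;
    double* ys = y.begin() + (std::size_t)s * Ho * Wo;
    for (int wI = 0; wI < W; ++wI)
      for (int hI = 0; hI < H; ++hI) {
        const double v = xs[(std::size_t)wI * H + hI];
        ys[(std::size_t)(2 * wI) * Ho + 2 * hI] = v;
        ys[(std::size_t)(2 * wI) * Ho + 2 * hI + 1] = v;
        ys[(std::size_t)(2 * wI + 1) * Ho + 2 * hI] = v;
        ys[(std::size_t)(2 * wI + 1) * Ho + 2 * hI + 1] = v;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector g) {
  IntegerVector gd = g.attr("dim");
  const int Ho = gd[0], Wo = gd[1], CN = gd[2] * gd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector y((std::size_t)H * W * CN);
  y.attr("dim") = IntegerVector::create(H, W, gd[2], gd[3]);
  for (int s = 0; s < CN; ++s) {
    const double* gs = g.begin() + (std::size_t)s * Ho * Wo;
    double* ys = y.begin() + (std::size_t)s * H * W;
    for (int wI = 0; wI < W; ++wI)
      for (int hI = 0; hI < H; ++hI)
        ys[(std::size_t)wI * H + hI] =
          gs[(std::size_t)(2 * wI) * Ho + 2 * hI] +
          gs[(std::size_t)(2 * wI) * Ho + 2 * hI + 1] +
          gs[(std::size_t)(2 * wI + 1) * Ho + 2 * hI] +
          gs[(std::size_t)(2 * wI + 1) * Ho + 2 * hI + 1];
  }
  return y;
}

// Bilinear resize, half-pixel (pixel-center) convention, edge clamped.
// [[Rcpp::export]]
NumericVector cpp_bilinear_resize(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], CN = xd[2] * xd[3];
  NumericVector y((std::size_t)Ho * Wo * CN);
  y.attr("dim") = IntegerVector::create(Ho, Wo, xd[2], xd[3]);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> fh(Ho), fw(Wo);
  for (int i = 0; i < Ho; ++i) {
    double src = (i + 0.5) * sh - 0.5;
    if (src < 0) src = 0;
    if (src > H - 1) src = H - 1;
    h0[i] = (int)std::floor(src);
    h1[i] = std::min(h0[i] + 1, H - 1);
    fh[i] = src - h0[i];
  }
  for (int j = 0; j < Wo; ++j) {
    double src = (j + 0.5) * sw - 0.5;
    if (src < 0) src = 0;
    if (src > W - 1) src = W - 1;
    w0[j] = (int)std::floor(src);
    w1[j] = std::min(w0[j] + 1, W - 1);
    fw[j] = src - w0[j];
  }
  for (int s = 0; s < CN; ++s) {
    const double* xs = x.begin() + (std::size_t)s * H * W;
    double* ys = y.begin() + (std::size_t)s * Ho * Wo;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double a = xs[(std::size_t)w0[j] * H + h0[i]];
        const double b = xs[(std::size_t)w0[j] * H + h1[i]];
        const double c = xs[(std::size_t)w1[j] * H + h0[i]];
        const double d = xs[(std::size_t)w1[j] * H + h1[i]];
        ys[(std::size_t)j * Ho + i] =
          (1 - fw[j]) * ((1 - fh[i]) * a + fh[i] * b) +
          fw[j] * ((1 - fh[i]) * c + fh[i] * d);
      }
  }
  return y;
}

static inline double reflect_coord(double v, int n) {
  // reflect about pixel centers; period 2n
  if (n == 1) return 0.0;
  const double p = 2.0 * n;
  v -= std::floor(v / p) * p;  // v in [0, p)
  if (v >= n) v = p - v - 1e-12;
  if (v > n - 1) v = n - 1;
  return v;
}

// Zoom about the image center then translate; bilinear sampling with
// reflection padding. shift_h/shift_w/zoom are per-sample vectors.
// [[Rcpp::export]]
NumericVector cpp_affine_sample(NumericVector x, NumericVector shift_h,
                                NumericVector shift_w, NumericVector zoom) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double ch = (H - 1) / 2.0, cw = (W - 1) / 2.0;
  for (int n = 0; n < N; ++n) {
    const double z = zoom[n], dh = shift_h[n], dw = shift_w[n];
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((std::size_t)n * C + c) * H * W;
      double* ys = y.begin() + ((std::size_t)n * C + c) * H * W;
      for (int j = 0; j < W; ++j) {
        const double swc = reflect_coord((j - cw) / z + cw - dw, W);
        // horizontal source is constant down a column
        const int w0 = (int)std::floor(swc);
        const int w1 = std::min(w0 + 1, W - 1);
        const double fw = swc - w0;
        for (int i = 0; i < H; ++i) {
          const double shc = reflect_coord((i - ch) / z + ch - dh, H);
          const int h0 = (int)std::floor(shc);
          const int h1 = std::min(h0 + 1, H - 1);
          const double fh = shc - h0;
          ys[(std::size_t)j * H + i] =
            (1 - fw) * ((1 - fh) * xs[(std::size_t)w0 * H + h0] +
                        fh * xs[(std::size_t)w0 * H + h1]) +
            fw * ((1 - fh) * xs[(std::size_t)w1 * H + h0] +
                  fh * xs[(std::size_t)w1 * H + h1]);
        }
      }
    }
  }
  return y;
}
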