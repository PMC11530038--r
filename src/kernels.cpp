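// Low-level numeric kernels for feature-map tensors.
//
// Layout convention throughout the package: a feature map is a dense
// rank-4 array with dim = c(H, W, C, N) so that the spatial index runs
// fastest in column-major storage.  Convolutions are stride-1 with
// "same" zero padding for odd kernels and are evaluated as im2col
// followed by a BLAS GEMM; backward passes recompute the patch matrix
// instead of caching it (memory stays flat during training).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

inline void dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a rank-4 array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Patch matrix for one sample: (H*W) x (kh*kw*C).  Column index
// r = ikh + kh*(ikw + kw*c) matches the column-major flattening of a
// weight array with dim c(kh, kw, Cin, Cout).
void im2col_one(const double* x, int H, int W, int C,
                int kh, int kw, arma::mat& P) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  P.set_size(static_cast<arma::uword>(H) * W,
             static_cast<arma::uword>(kh) * kw * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + static_cast<size_t>(c) * H * W;
    for (int ikw = 0; ikw < kw; ++ikw) {
      for (int ikh = 0; ikh < kh; ++ikh) {
        const arma::uword col = ikh + kh * (ikw + kw * c);
        double* pc = P.colptr(col);
        const int dh = ikh - ph, dw = ikw - pw;
        // source pixel (h + dh, w + dw); zero outside
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
        if (h0 > 0 || h1 < H || w0 > 0 || w1 < W) {
          std::fill(pc, pc + static_cast<size_t>(H) * W, 0.0);
        }
        for (int w = w0; w < w1; ++w) {
          const double* src = xc + static_cast<size_t>(w + dw) * H + (h0 + dh);
          double* dst = pc + static_cast<size_t>(w) * H + h0;
          std::copy(src, src + (h1 - h0), dst);
        }
      }
    }
  }
}

// Scatter-add of a patch-gradient matrix back onto the input gradient.
void col2im_one(const arma::mat& Pg, int H, int W, int C,
                int kh, int kw, double* gx) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + static_cast<size_t>(c) * H * W;
    for (int ikw = 0; ikw < kw; ++ikw) {
      for (int ikh = 0; ikh < kh; ++ikh) {
        const arma::uword col = ikh + kh * (ikw + kw * c);
        const double* pc = Pg.colptr(col);
        const int dh = ikh - ph, dw = ikw - pw;
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
        for (int w = w0; w < w1; ++w) {
          double* dst = gc + static_cast<size_t>(w + dw) * H + (h0 + dh);
          const double* src = pc + static_cast<size_t>(w) * H + h0;
          for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".cpp_conv2d_fw")]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weights must have dim (kh, kw, Cin, Cout)");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  if (kh % 2 == 0 || kw % 2 == 0) stop("conv2d: only odd kernel sizes");

  const arma::uword HW = static_cast<arma::uword>(H) * W;
  arma::mat Wm(const_cast<double*>(w.begin()),
               static_cast<arma::uword>(kh) * kw * C, Cout, false, true);
  NumericVector y(HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);

  arma::mat P;
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + static_cast<size_t>(n) * HW * C, H, W, C, kh, kw, P);
    arma::mat Yn(y.begin() + static_cast<size_t>(n) * HW * Cout, HW, Cout,
                 false, true);
    Yn = P * Wm;
    for (int co = 0; co < Cout; ++co) Yn.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bw")]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const arma::uword HW = static_cast<arma::uword>(H) * W;

  arma::mat Wm(const_cast<double*>(w.begin()),
               static_cast<arma::uword>(kh) * kw * C, Cout, false, true);
  arma::vec Gb(Cout, arma::fill::zeros);
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");

  arma::mat Gw(Wm.n_rows, Wm.n_cols, arma::fill::zeros);
  arma::mat P, Pg;
  for (int n = 0; n < N; ++n) {
    arma::mat Gy(const_cast<double*>(gy.begin()) + static_cast<size_t>(n) * HW * Cout,
                 HW, Cout, false, true);
    im2col_one(x.begin() + static_cast<size_t>(n) * HW * C, H, W, C, kh, kw, P);
    Gw += P.t() * Gy;
    Gb += arma::sum(Gy, 0).t();
    Pg = Gy * Wm.t();
    col2im_one(Pg, H, W, C, kh, kw, gx.begin() + static_cast<size_t>(n) * HW * C);
  }

  NumericVector gwv(Gw.begin(), Gw.end());
  gwv.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(Gb.begin(), Gb.end()));
}

// 2x2 average pooling, stride 2 (odd trailing row/column dropped).
// [[Rcpp::export(name = ".cpp_avgpool2_fw")]]
NumericVector cpp_avgpool2_fw(NumericVector x) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<size_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const size_t planes = static_cast<size_t>(C) * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* xp = x.begin() + p * H * W;
    double* yp = y.begin() + p * Ho * Wo;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const double* c0 = xp + static_cast<size_t>(2 * w) * H + 2 * h;
        const double* c1 = c0 + H;
        yp[static_cast<size_t>(w) * Ho + h] =
            0.25 * (c0[0] + c0[1] + c1[0] + c1[1]);
      }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_avgpool2_bw")]]
NumericVector cpp_avgpool2_bw(NumericVector gy, int H, int W) {
  IntegerVector d = gy.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector gx(static_cast<size_t>(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const size_t planes = static_cast<size_t>(C) * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* gp = gy.begin() + p * Ho * Wo;
    double* xp = gx.begin() + p * H * W;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const double g = 0.25 * gp[static_cast<size_t>(w) * Ho + h];
        double* c0 = xp + static_cast<size_t>(2 * w) * H + 2 * h;
        double* c1 = c0 + H;
        c0[0] += g; c0[1] += g; c1[0] += g; c1[1] += g;
      }
  }
  return gx;
}

namespace {
// Half-pixel-center source coordinates (align_corners = FALSE).
inline void lin_coeff(int out, int in, std::vector<int>& i0,
                      std::vector<int>& i1, std::vector<double>& w1) {
  i0.resize(out); i1.resize(out); w1.resize(out);
  const double scale = static_cast<double>(in) / out;
  for (int i = 0; i < out; ++i) {
    double s = (i + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    int lo = static_cast<int>(std::floor(s));
    if (lo > in - 1) lo = in - 1;
    int hi = std::min(lo + 1, in - 1);
    i0[i] = lo; i1[i] = hi; w1[i] = s - lo;
    if (w1[i] < 0) w1[i] = 0;
    if (w1[i] > 1) w1[i] = 1;
  }
}
}  // namespace

// [[Rcpp::export(name = ".cpp_resize_bilinear_fw")]]
NumericVector cpp_resize_bilinear_fw(NumericVector x, int Ho, int Wo) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> hw, ww;
  lin_coeff(Ho, H, h0, h1, hw);
  lin_coeff(Wo, W, w0, w1, ww);
  NumericVector y(static_cast<size_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const size_t planes = static_cast<size_t>(C) * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* xp = x.begin() + p * H * W;
    double* yp = y.begin() + p * Ho * Wo;
    for (int w = 0; w < Wo; ++w) {
      const double* ca = xp + static_cast<size_t>(w0[w]) * H;
      const double* cb = xp + static_cast<size_t>(w1[w]) * H;
      const double bw = ww[w];
      for (int h = 0; h < Ho; ++h) {
        const double bh = hw[h];
        const double top = (1 - bw) * ca[h0[h]] + bw * cb[h0[h]];
        const double bot = (1 - bw) * ca[h1[h]] + bw * cb[h1[h]];
        yp[static_cast<size_t>(w) * Ho + h] = (1 - bh) * top + bh * bot;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_resize_bilinear_bw")]]
NumericVector cpp_resize_bilinear_bw(NumericVector gy, int H, int W) {
  IntegerVector d = gy.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> hw, ww;
  lin_coeff(Ho, H, h0, h1, hw);
  lin_coeff(Wo, W, w0, w1, ww);
  NumericVector gx(static_cast<size_t>(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const size_t planes = static_cast<size_t>(C) * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* gp = gy.begin() + p * Ho * Wo;
    double* xp = gx.begin() + p * H * W;
    for (int w = 0; w < Wo; ++w) {
      double* ca = xp + static_cast<size_t>(w0[w]) * H;
      double* cb = xp + static_cast<size_t>(w1[w]) * H;
      const double bw = ww[w];
      for (int h = 0; h < Ho; ++h) {
        const double g = gp[static_cast<size_t>(w) * Ho + h];
        const double bh = hw[h];
        ca[h0[h]] += (1 - bw) * (1 - bh) * g;
        cb[h0[h]] += bw * (1 - bh) * g;
        ca[h1[h]] += (1 - bw) * bh * g;
        cb[h1[h]] += bw * bh * g;
      }
    }
  }
  return gx;
}

// Global max pooling: values (C x N) plus the flat argmax per plane.
// [[Rcpp::export(name = ".cpp_gmp_fw")]]
List cpp_gmp_fw(NumericVector x) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  const size_t HW = static_cast<size_t>(H) * W;
  NumericMatrix v(C, N);
  IntegerMatrix idx(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + (static_cast<size_t>(n) * C + c) * HW;
      size_t best = 0;
      for (size_t i = 1; i < HW; ++i)
        if (p[i] > p[best]) best = i;
      v(c, n) = p[best];
      idx(c, n) = static_cast<int>(best);
    }
  return List::create(_["value"] = v, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_relu_fw")]]
NumericVector cpp_relu_fw(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// [[Rcpp::export(name = ".cpp_relu_bw")]]
NumericVector cpp_relu_bw(NumericVector x, NumericVector g) {
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* op = gx.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) op[i] = xp[i] > 0 ? gp[i] : 0;
  return gx;
}

// Batch norm forward (training or eval).  Returns y, xhat, inv_std and
// the batch mean/var so the R wrapper can update running statistics.
// [[Rcpp::export(name = ".cpp_bn_fw")]]
List cpp_bn_fw(NumericVector x, NumericVector gamma, NumericVector beta,
               NumericVector use_mean, NumericVector use_var,
               bool training, double eps) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  const size_t HW = static_cast<size_t>(H) * W;
  const double m = static_cast<double>(HW) * N;
  arma::vec mu(C), va(C);
  if (training) {
    mu.zeros(); va.zeros();
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        const double* p = x.begin() + (static_cast<size_t>(n) * C + c) * HW;
        double s = 0, s2 = 0;
        for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
        mu[c] += s; va[c] += s2;
      }
    mu /= m;
    va = va / m - mu % mu;
    va.transform([](double v) { return v < 0 ? 0 : v; });
  } else {
    mu = arma::vec(use_mean.begin(), C);
    va = arma::vec(use_var.begin(), C);
  }
  arma::vec inv_std = 1.0 / arma::sqrt(va + eps);
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + (static_cast<size_t>(n) * C + c) * HW;
      double* xh = xhat.begin() + (static_cast<size_t>(n) * C + c) * HW;
      double* yp = y.begin() + (static_cast<size_t>(n) * C + c) * HW;
      const double mc = mu[c], is = inv_std[c], ga = gamma[c], be = beta[c];
      for (size_t i = 0; i < HW; ++i) {
        xh[i] = (p[i] - mc) * is;
        yp[i] = ga * xh[i] + be;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat,
                      _["inv_std"] = NumericVector(inv_std.begin(), inv_std.end()),
                      _["mean"] = NumericVector(mu.begin(), mu.end()),
                      _["var"] = NumericVector(va.begin(), va.end()));
}

// [[Rcpp::export(name = ".cpp_bn_bw")]]
List cpp_bn_bw(NumericVector xhat, NumericVector g, NumericVector gamma,
               NumericVector inv_std, bool training) {
  IntegerVector d = g.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = static_cast<size_t>(H) * W;
  const double m = static_cast<double>(HW) * N;
  arma::vec gbeta(C, arma::fill::zeros), ggamma(C, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gp = g.begin() + (static_cast<size_t>(n) * C + c) * HW;
      const double* xh = xhat.begin() + (static_cast<size_t>(n) * C + c) * HW;
      double sb = 0, sg = 0;
      for (size_t i = 0; i < HW; ++i) { sb += gp[i]; sg += gp[i] * xh[i]; }
      gbeta[c] += sb; ggamma[c] += sg;
    }
  NumericVector gx(g.size());
  gx.attr("dim") = g.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gp = g.begin() + (static_cast<size_t>(n) * C + c) * HW;
      const double* xh = xhat.begin() + (static_cast<size_t>(n) * C + c) * HW;
      double* op = gx.begin() + (static_cast<size_t>(n) * C + c) * HW;
      const double k = gamma[c] * inv_std[c];
      if (training) {
        const double gb = gbeta[c] / m, gg = ggamma[c] / m;
        for (size_t i = 0; i < HW; ++i)
          op[i] = k * (gp[i] - gb - xh[i] * gg);
      } else {
        for (size_t i = 0; i < HW; ++i) op[i] = k * gp[i];
      }
    }
  return List::create(_["gx"] = gx,
                      _["ggamma"] = NumericVector(ggamma.begin(), ggamma.end()),
                      _["gbeta"] = NumericVector(gbeta.begin(), gbeta.end()));
}

// Channel concatenation of a list of (H, W, Ci, N) arrays.
// [[Rcpp::export(name = ".cpp_concat_ch")]]
NumericVector cpp_concat_ch(List xs) {
  const int K = xs.size();
  std::vector<NumericVector> vs(K);
  std::vector<int> cc(K);
  int H = 0, W = 0, N = 0, Ct = 0;
  for (int k = 0; k < K; ++k) {
    vs[k] = as<NumericVector>(xs[k]);
    int h, w, c, n;
    dims4(vs[k], h, w, c, n);
    if (k == 0) { H = h; W = w; N = n; }
    else if (h != H || w != W || n != N) stop("concat: shape mismatch");
    cc[k] = c; Ct += c;
  }
  NumericVector y(static_cast<size_t>(H) * W * Ct * N);
  y.attr("dim") = IntegerVector::create(H, W, Ct, N);
  const size_t HW = static_cast<size_t>(H) * W;
  for (int n = 0; n < N; ++n) {
    double* yp = y.begin() + static_cast<size_t>(n) * HW * Ct;
    for (int k = 0; k < K; ++k) {
      const double* xp = vs[k].begin() + static_cast<size_t>(n) * HW * cc[k];
      std::copy(xp, xp + HW * cc[k], yp);
      yp += HW * cc[k];
    }
  }
  return y;
}

// Slice channels [c0, c0+nc) out of a (H, W, C, N) array.
// [[Rcpp::export(name = ".cpp_slice_ch")]]
NumericVector cpp_slice_ch(NumericVector x, int c0, int nc) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  const size_t HW = static_cast<size_t>(H) * W;
  NumericVector y(HW * nc * N);
  y.attr("dim") = IntegerVector::create(H, W, nc, N);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (static_cast<size_t>(n) * C + c0) * HW;
    double* yp = y.begin() + static_cast<size_t>(n) * HW * nc;
    std::copy(xp, xp + HW * nc, yp);
  }
  return y;
}

// y = x * s with s a (C, N) matrix of per-channel coefficients.
// [[Rcpp::export(name = ".cpp_mul_channel")]]
NumericVector cpp_mul_channel(NumericVector x, NumericMatrix s) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  const size_t HW = static_cast<size_t>(H) * W;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (static_cast<size_t>(n) * C + c) * HW;
      double* yp = y.begin() + (static_cast<size_t>(n) * C + c) * HW;
      const double k = s(c, n);
      for (size_t i = 0; i < HW; ++i) yp[i] = xp[i] * k;
    }
  return y;
}

// per-channel-per-sample sums of a*b -> (C, N)
// [[Rcpp::export(name = ".cpp_dot_channel")]]
NumericMatrix cpp_dot_channel(NumericVector a, NumericVector b) {
  int H, W, C, N;
  dims4(a, H, W, C, N);
  const size_t HW = static_cast<size_t>(H) * W;
  NumericMatrix out(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* ap = a.begin() + (static_cast<size_t>(n) * C + c) * HW;
      const double* bp = b.begin() + (static_cast<size_t>(n) * C + c) * HW;
      double s = 0;
      for (size_t i = 0; i < HW; ++i) s += ap[i] * bp[i];
      out(c, n) = s;
    }
  return out;
}

// y = x * a with a a (H, W, 1, N) per-pixel coefficient map
// [[Rcpp::export(name = ".cpp_mul_spatial")]]
NumericVector cpp_mul_spatial(NumericVector x, NumericVector a) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  const size_t HW = static_cast<size_t>(H) * W;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n) {
    const double* ap = a.begin() + static_cast<size_t>(n) * HW;
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (static_cast<size_t>(n) * C + c) * HW;
      double* yp = y.begin() + (static_cast<size_t>(n) * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) yp[i] = xp[i] * ap[i];
    }
  }
  return y;
}

// sum over channels of a*b -> (H, W, 1, N)
// [[Rcpp::export(name = ".cpp_dot_spatial")]]
NumericVector cpp_dot_spatial(NumericVector a, NumericVector b) {
  int H, W, C, N;
  dims4(a, H, W, C, N);
  const size_t HW = static_cast<size_t>(H) * W;
  NumericVector out(HW * N);
  out.attr("dim") = IntegerVector::create(H, W, 1, N);
  for (int n = 0; n < N; ++n) {
    double* op = out.begin() + static_cast<size_t>(n) * HW;
    for (int c = 0; c < C; ++c) {
      const double* ap = a.begin() + (static_cast<size_t>(n) * C + c) * HW;
      const double* bp = b.begin() + (static_cast<size_t>(n) * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) op[i] += ap[i] * bp[i];
    }
  }
  return out;
}
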