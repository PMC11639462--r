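// Dense numeric kernels for the network modules: 2-D convolution (grouped,
// strided, padded) with its backward pass, max/average pooling, and bilinear
// grid sampling. Feature maps are R arrays with dim (H, W, C, N), column-major.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// im2col for one image, one channel group.
// col is (k*k*Cg) x (Ho*Wo); channels iterate slowest within a column.
static void im2col(const double* x, int H, int W, int Cg, int c0,
                   int k, int stride, int pad, int Ho, int Wo, arma::mat& col) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int colidx = ho + Ho * wo;
      double* dst = col.colptr(colidx);
      for (int c = 0; c < Cg; ++c) {
        const double* xc = x + (size_t)(c0 + c) * H * W;
        for (int kj = 0; kj < k; ++kj) {
          int w = wo * stride - pad + kj;
          for (int ki = 0; ki < k; ++ki) {
            int h = ho * stride - pad + ki;
            double v = 0.0;
            if (h >= 0 && h < H && w >= 0 && w < W) v = xc[h + (size_t)H * w];
            dst[ki + k * (kj + k * c)] = v;
          }
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& col, double* gx, int H, int W, int Cg,
                       int c0, int k, int stride, int pad, int Ho, int Wo) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int colidx = ho + Ho * wo;
      const double* src = col.colptr(colidx);
      for (int c = 0; c < Cg; ++c) {
        double* xc = gx + (size_t)(c0 + c) * H * W;
        for (int kj = 0; kj < k; ++kj) {
          int w = wo * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int h = ho * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            xc[h + (size_t)H * w] += src[ki + k * (kj + k * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w,
                         Nullable<NumericVector> bias,
                         int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cg = wd[2], Cout = wd[3];
  if (C != Cg * groups) stop("channel/group mismatch in conv2d");
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  int Coutg = Cout / groups;
  NumericVector y(Ho * (size_t)Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cg, Cout, false, true);
  arma::mat col((size_t)k * k * Cg, (size_t)Ho * Wo);
  bool has_b = bias.isNotNull();
  NumericVector bv;
  if (has_b) bv = bias.get();
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    double* yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, Cg, g * Cg, k, stride, pad, Ho, Wo, col);
      arma::mat Wg = Wm.cols(g * Coutg, (g + 1) * Coutg - 1);
      arma::mat Yt = col.t() * Wg;  // (Ho*Wo) x Coutg
      for (int c = 0; c < Coutg; ++c) {
        double b = has_b ? bv[g * Coutg + c] : 0.0;
        double* dst = yn + (size_t)(g * Coutg + c) * Ho * Wo;
        const double* src = Yt.colptr(c);
        for (size_t i = 0; i < (size_t)Ho * Wo; ++i) dst[i] = src[i] + b;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, int groups, bool need_gx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cg = wd[2], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  int Coutg = Cout / groups;
  NumericVector gx(x.size()), gw(w.size()), gb(Cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cg, Cout, false, true);
  arma::mat Gw(gw.begin(), (size_t)k * k * Cg, Cout, false, true);
  arma::mat col((size_t)k * k * Cg, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    const double* gyn = gy.begin() + (size_t)n * Ho * Wo * Cout;
    double* gxn = gx.begin() + (size_t)n * H * W * C;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, Cg, g * Cg, k, stride, pad, Ho, Wo, col);
      arma::mat Gy(const_cast<double*>(gyn) + (size_t)g * Coutg * Ho * Wo,
                   (size_t)Ho * Wo, Coutg, false, true);
      Gw.cols(g * Coutg, (g + 1) * Coutg - 1) += col * Gy;
      if (need_gx) {
        arma::mat gcol = Wm.cols(g * Coutg, (g + 1) * Coutg - 1) * Gy.t();
        col2im_acc(gcol, gxn, H, W, Cg, g * Cg, k, stride, pad, Ho, Wo);
      }
      for (int c = 0; c < Coutg; ++c)
        gb[g * Coutg + c] += arma::accu(Gy.col(c));
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// type: 0 = max (returns argmax), 1 = average over valid (non-padded) taps.
// [[Rcpp::export]]
List cpp_pool2d(NumericVector x, int k, int stride, int pad, int type) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg(type == 0 ? y.size() : 0);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -INFINITY, acc = 0.0;
          int besti = -1, cnt = 0;
          for (int kj = 0; kj < k; ++kj) {
            int w = wo * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int h = ho * stride - pad + ki;
              if (h < 0 || h >= H) continue;
              double v = xc[h + (size_t)H * w];
              if (type == 0) {
                if (v > best) { best = v; besti = h + H * w; }
              } else { acc += v; ++cnt; }
            }
          }
          size_t oi = (size_t)ho + Ho * ((size_t)wo + (size_t)Wo * ((size_t)c + (size_t)C * n));
          if (type == 0) { y[oi] = best; arg[oi] = besti; }
          else y[oi] = acc / cnt;
          (void)o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_pool2d_bwd(NumericVector gy, IntegerVector xdim, int k,
                             int stride, int pad, int type, IntegerVector argmax) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector yd = gy.attr("dim");
  int Ho = yd[0], Wo = yd[1];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* gxc = gx.begin() + ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          size_t oi = (size_t)ho + Ho * ((size_t)wo + (size_t)Wo * ((size_t)c + (size_t)C * n));
          double g = gy[oi];
          if (g == 0) continue;
          if (type == 0) {
            gxc[argmax[oi]] += g;
          } else {
            int cnt = 0;
            for (int kj = 0; kj < k; ++kj) {
              int w = wo * stride - pad + kj;
              if (w < 0 || w >= W) continue;
              for (int ki = 0; ki < k; ++ki) {
                int h = ho * stride - pad + ki;
                if (h >= 0 && h < H) ++cnt;
              }
            }
            double share = g / cnt;
            for (int kj = 0; kj < k; ++kj) {
              int w = wo * stride - pad + kj;
              if (w < 0 || w >= W) continue;
              for (int ki = 0; ki < k; ++ki) {
                int h = ho * stride - pad + ki;
                if (h >= 0 && h < H) gxc[h + (size_t)H * w] += share;
              }
            }
          }
        }
      }
    }
  }
  return gx;
}

// Bilinear sampling of x (H,W,C,N) at continuous 0-based pixel positions
// (cy, cx), each (Ho,Wo,N). Border-clamped. Returns (Ho,Wo,C,N).
// [[Rcpp::export]]
NumericVector cpp_grid_sample(NumericVector x, NumericVector cy, NumericVector cx) {
  IntegerVector xd = x.attr("dim"), cd = cy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = cd[0], Wo = cd[1];
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    const double* cyn = cy.begin() + (size_t)n * Ho * Wo;
    const double* cxn = cx.begin() + (size_t)n * Ho * Wo;
    for (size_t p = 0; p < (size_t)Ho * Wo; ++p) {
      double fy = cyn[p], fx = cxn[p];
      if (fy < 0) fy = 0; if (fy > H - 1) fy = H - 1;
      if (fx < 0) fx = 0; if (fx > W - 1) fx = W - 1;
      int y0 = (int)std::floor(fy), x0 = (int)std::floor(fx);
      if (y0 > H - 2) y0 = H - 2; if (y0 < 0) y0 = 0;
      if (x0 > W - 2) x0 = W - 2; if (x0 < 0) x0 = 0;
      double dy = fy - y0, dx = fx - x0;
      for (int c = 0; c < C; ++c) {
        const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
        double v00 = xc[y0 + (size_t)H * x0], v10 = xc[y0 + 1 + (size_t)H * x0];
        double v01 = xc[y0 + (size_t)H * (x0 + 1)], v11 = xc[y0 + 1 + (size_t)H * (x0 + 1)];
        y[p + (size_t)Ho * Wo * ((size_t)c + (size_t)C * n)] =
          (1 - dy) * (1 - dx) * v00 + dy * (1 - dx) * v10 +
          (1 - dy) * dx * v01 + dy * dx * v11;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_grid_sample_bwd(NumericVector x, NumericVector cy, NumericVector cx,
                         NumericVector gy) {
  IntegerVector xd = x.attr("dim"), cd = cy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = cd[0], Wo = cd[1];
  NumericVector gx(x.size()), gcy(cy.size()), gcx(cx.size());
  gx.attr("dim") = xd; gcy.attr("dim") = cd; gcx.attr("dim") = cd;
  for (int n = 0; n < N; ++n) {
    const double* cyn = cy.begin() + (size_t)n * Ho * Wo;
    const double* cxn = cx.begin() + (size_t)n * Ho * Wo;
    for (size_t p = 0; p < (size_t)Ho * Wo; ++p) {
      double fy = cyn[p], fx = cxn[p];
      bool in_y = (fy > 0 && fy < H - 1), in_x = (fx > 0 && fx < W - 1);
      if (fy < 0) fy = 0; if (fy > H - 1) fy = H - 1;
      if (fx < 0) fx = 0; if (fx > W - 1) fx = W - 1;
      int y0 = (int)std::floor(fy), x0 = (int)std::floor(fx);
      if (y0 > H - 2) y0 = H - 2; if (y0 < 0) y0 = 0;
      if (x0 > W - 2) x0 = W - 2; if (x0 < 0) x0 = 0;
      double dy = fy - y0, dx = fx - x0;
      double acc_cy = 0, acc_cx = 0;
      for (int c = 0; c < C; ++c) {
        const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
        double* gxc = gx.begin() + ((size_t)n * C + c) * H * W;
        double g = gy[p + (size_t)Ho * Wo * ((size_t)c + (size_t)C * n)];
        if (g == 0) continue;
        double v00 = xc[y0 + (size_t)H * x0], v10 = xc[y0 + 1 + (size_t)H * x0];
        double v01 = xc[y0 + (size_t)H * (x0 + 1)], v11 = xc[y0 + 1 + (size_t)H * (x0 + 1)];
        gxc[y0 + (size_t)H * x0]       += g * (1 - dy) * (1 - dx);
        gxc[y0 + 1 + (size_t)H * x0]   += g * dy * (1 - dx);
        gxc[y0 + (size_t)H * (x0 + 1)] += g * (1 - dy) * dx;
        gxc[y0 + 1 + (size_t)H * (x0 + 1)] += g * dy * dx;
        acc_cy += g * ((1 - dx) * (v10 - v00) + dx * (v11 - v01));
        acc_cx += g * ((1 - dy) * (v01 - v00) + dy * (v11 - v10));
      }
      gcy[p + (size_t)Ho * Wo * n] = in_y ? acc_cy : 0.0;
      gcx[p + (size_t)Ho * Wo * n] = in_x ? acc_cx : 0.0;
    }
  }
  return List::create(_["gx"] = gx, _["gcy"] = gcy, _["gcx"] = gcx);
}
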