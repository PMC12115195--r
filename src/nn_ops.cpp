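// Core dense kernels for the CPU conv-net engine.
// Tensor layout throughout: H x W x C x N column-major R arrays.
// Weight layout: kh x kw x (Cin/groups) x Cout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector make4(R_xlen_t a, R_xlen_t b, R_xlen_t c, R_xlen_t d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create((int)a, (int)b, (int)c, (int)d);
  return v;
}

static inline int out_dim(int in, int k, int stride, int dil, int p0, int p1) {
  return (in + p0 + p1 - dil * (k - 1) - 1) / stride + 1;
}

// im2col for one image and one channel group.
// col: (kh*kw*cpg) x (Ho*Wo), row index r = dh + kh*(dw + kw*ic)
static void im2col(const double* x, int H, int W, int cpg, int c0,
                   int kh, int kw, int stride, int dil,
                   int pt, int pl, int Ho, int Wo, arma::mat& col) {
  const long HW = (long)H * W;
  for (int ic = 0; ic < cpg; ++ic) {
    const double* xc = x + (long)(c0 + ic) * HW;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        int r = dh + kh * (dw + kw * ic);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pl + dw * dil;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) col(r, ho + (long)Ho * wo) = 0.0;
            continue;
          }
          const double* xcol = xc + (long)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pt + dh * dil;
            col(r, ho + (long)Ho * wo) =
              (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, double* x, int H, int W, int cpg, int c0,
                   int kh, int kw, int stride, int dil,
                   int pt, int pl, int Ho, int Wo) {
  const long HW = (long)H * W;
  for (int ic = 0; ic < cpg; ++ic) {
    double* xc = x + (long)(c0 + ic) * HW;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        int r = dh + kh * (dw + kw * ic);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pl + dw * dil;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (long)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pt + dh * dil;
            if (hi < 0 || hi >= H) continue;
            xcol[hi] += col(r, ho + (long)Ho * wo);
          }
        }
      }
    }
  }
}


// direct depthwise path (groups == C, one output channel per input channel)
static void dw_fwd(const double* x, const double* w, double* y,
                   int H, int W, int C, int kh, int kw, int stride, int dil,
                   int pt, int pl, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (long)c * H * W;
    const double* wc = w + (long)c * kh * kw;
    double* yc = y + (long)c * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double acc = 0.0;
        for (int dw_ = 0; dw_ < kw; ++dw_) {
          int wi = wo * stride - pl + dw_ * dil;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + (long)wi * H;
          const double* wcol = wc + (long)dw_ * kh;
          for (int dh = 0; dh < kh; ++dh) {
            int hi = ho * stride - pt + dh * dil;
            if (hi >= 0 && hi < H) acc += xcol[hi] * wcol[dh];
          }
        }
        yc[ho + (long)Ho * wo] = acc;
      }
    }
  }
}

static void dw_bwd(const double* x, const double* w, const double* dy,
                   double* dx, double* dwt,
                   int H, int W, int C, int kh, int kw, int stride, int dil,
                   int pt, int pl, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (long)c * H * W;
    const double* wc = w + (long)c * kh * kw;
    const double* dyc = dy + (long)c * Ho * Wo;
    double* dxc = dx + (long)c * H * W;
    double* dwc = dwt + (long)c * kh * kw;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double g = dyc[ho + (long)Ho * wo];
        if (g == 0.0) continue;
        for (int dw_ = 0; dw_ < kw; ++dw_) {
          int wi = wo * stride - pl + dw_ * dil;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + (long)wi * H;
          double* dxcol = dxc + (long)wi * H;
          for (int dh = 0; dh < kh; ++dh) {
            int hi = ho * stride - pt + dh * dil;
            if (hi >= 0 && hi < H) {
              dxcol[hi] += g * wc[dh + (long)dw_ * kh];
              dwc[dh + (long)dw_ * kh] += g * xcol[hi];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector bias,
                         int stride, int dil,
                         int pt, int pb, int pl, int pr, int groups,
                         bool has_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], cpg = wd[2], Cout = wd[3];
  if (C != cpg * groups) stop("conv2d: channel/group mismatch");
  int copg = Cout / groups;
  int Ho = out_dim(H, kh, stride, dil, pt, pb);
  int Wo = out_dim(W, kw, stride, dil, pl, pr);
  if (Ho < 1 || Wo < 1) stop("conv2d: non-positive output size");
  NumericVector y = make4(Ho, Wo, Cout, N);
  if (groups == C && cpg == 1 && Cout == C) {
    for (int n = 0; n < N; ++n)
      dw_fwd(x.begin() + (long)H * W * C * n, w.begin(),
             y.begin() + (long)Ho * Wo * Cout * n,
             H, W, C, kh, kw, stride, dil, pt, pl, Ho, Wo);
    if (has_bias)
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < Cout; ++c) {
          double* yc = y.begin() + (long)Ho * Wo * (c + (long)Cout * n);
          for (long p = 0; p < (long)Ho * Wo; ++p) yc[p] += bias[c];
        }
    return y;
  }
  const int K = kh * kw * cpg;
  const long HoWo = (long)Ho * Wo;
  arma::mat col(K, HoWo);
  for (int g = 0; g < groups; ++g) {
    // weight slice for group g: columns copg*g .. copg*(g+1)-1
    arma::mat Wg(const_cast<double*>(w.begin()) + (long)K * copg * g, K, copg, false, true);
    for (int n = 0; n < N; ++n) {
      const double* xn = x.begin() + (long)H * W * C * n;
      im2col(xn, H, W, cpg, g * cpg, kh, kw, stride, dil, pt, pl, Ho, Wo, col);
      arma::mat Yg(y.begin() + (long)Ho * Wo * (g * copg) + (long)Ho * Wo * Cout * n,
                   HoWo, copg, false, true);
      Yg = col.t() * Wg;
      if (has_bias)
        for (int oc = 0; oc < copg; ++oc)
          Yg.col(oc) += bias[g * copg + oc];
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int dil,
                int pt, int pb, int pl, int pr, int groups,
                bool has_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], cpg = wd[2], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  int copg = Cout / groups;
  const int K = kh * kw * cpg;
  const long HoWo = (long)Ho * Wo;

  NumericVector dx = make4(H, W, C, N);
  NumericVector dw = make4(kh, kw, cpg, Cout);
  NumericVector db(has_bias ? Cout : 1);
  if (groups == C && cpg == 1 && Cout == C) {
    for (int n = 0; n < N; ++n)
      dw_bwd(x.begin() + (long)H * W * C * n, w.begin(),
             dy.begin() + HoWo * Cout * n,
             dx.begin() + (long)H * W * C * n, dw.begin(),
             H, W, C, kh, kw, stride, dil, pt, pl, Ho, Wo);
    if (has_bias)
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < Cout; ++c) {
          const double* dyc = dy.begin() + HoWo * (c + (long)Cout * n);
          for (long p = 0; p < HoWo; ++p) db[c] += dyc[p];
        }
    return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
  }
  arma::mat col(K, HoWo);
  for (int g = 0; g < groups; ++g) {
    arma::mat Wg(const_cast<double*>(w.begin()) + (long)K * copg * g, K, copg, false, true);
    arma::mat dWg(dw.begin() + (long)K * copg * g, K, copg, false, true);
    for (int n = 0; n < N; ++n) {
      const double* xn = x.begin() + (long)H * W * C * n;
      arma::mat dYg(const_cast<double*>(dy.begin()) + HoWo * (g * copg) + HoWo * Cout * n,
                    HoWo, copg, false, true);
      im2col(xn, H, W, cpg, g * cpg, kh, kw, stride, dil, pt, pl, Ho, Wo, col);
      dWg += col * dYg;
      arma::mat dcol = Wg * dYg.t();                  // K x HoWo
      col2im(dcol, dx.begin() + (long)H * W * C * n, H, W, cpg, g * cpg,
             kh, kw, stride, dil, pt, pl, Ho, Wo);
      if (has_bias)
        for (int oc = 0; oc < copg; ++oc)
          db[g * copg + oc] += arma::accu(dYg.col(oc));
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Max pooling, stride-1 or strided, -Inf padding semantics.
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int k, int stride, int pt, int pl) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = (H + 2 * pt - k) / stride + 1;  // symmetric pad assumed (pt==pb)
  int Wo = (W + 2 * pl - k) / stride + 1;
  NumericVector y = make4(Ho, Wo, C, N);
  IntegerVector arg(y.size());
  const long HW = (long)H * W;
  long oi = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + HW * (c + (long)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf; long bidx = -1;
          for (int dw = 0; dw < k; ++dw) {
            int wi = wo * stride - pl + dw;
            if (wi < 0 || wi >= W) continue;
            for (int dh = 0; dh < k; ++dh) {
              int hi = ho * stride - pt + dh;
              if (hi < 0 || hi >= H) continue;
              double v = xc[hi + (long)H * wi];
              if (v > best) { best = v; bidx = hi + (long)H * wi; }
            }
          }
          oi = (long)ho + Ho * ((long)wo + Wo * ((long)c + (long)C * n));
          y[oi] = best;
          arg[oi] = (int)bidx;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector arg,
                          int H, int W, int C, int N) {
  NumericVector dx = make4(H, W, C, N);
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1];
  const long HW = (long)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      long base = HW * (c + (long)C * n);
      for (long p = 0; p < (long)Ho * Wo; ++p) {
        long oi = p + (long)Ho * Wo * (c + (long)C * n);
        if (arg[oi] >= 0) dx[base + arg[oi]] += dy[oi];
      }
    }
  return dx;
}

// Average pooling excluding padded cells.
// [[Rcpp::export(name = ".avgpool_fwd")]]
NumericVector avgpool_fwd(NumericVector x, int k, int stride, int pt, int pl) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = (H + 2 * pt - k) / stride + 1;
  int Wo = (W + 2 * pl - k) / stride + 1;
  NumericVector y = make4(Ho, Wo, C, N);
  const long HW = (long)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + HW * (c + (long)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double s = 0.0; int cnt = 0;
          for (int dw = 0; dw < k; ++dw) {
            int wi = wo * stride - pl + dw;
            if (wi < 0 || wi >= W) continue;
            for (int dh = 0; dh < k; ++dh) {
              int hi = ho * stride - pt + dh;
              if (hi < 0 || hi >= H) continue;
              s += xc[hi + (long)H * wi]; ++cnt;
            }
          }
          y[(long)ho + Ho * ((long)wo + Wo * ((long)c + (long)C * n))] =
            cnt > 0 ? s / cnt : 0.0;
        }
    }
  return y;
}

// [[Rcpp::export(name = ".avgpool_bwd")]]
NumericVector avgpool_bwd(NumericVector dy, int k, int stride, int pt, int pl,
                          int H, int W, int C, int N) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx = make4(H, W, C, N);
  const long HW = (long)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + HW * (c + (long)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          int cnt = 0;
          for (int dw = 0; dw < k; ++dw) {
            int wi = wo * stride - pl + dw;
            if (wi < 0 || wi >= W) continue;
            for (int dh = 0; dh < k; ++dh) {
              int hi = ho * stride - pt + dh;
              if (hi >= 0 && hi < H) ++cnt;
            }
          }
          if (cnt == 0) continue;
          double g = dy[(long)ho + Ho * ((long)wo + Wo * ((long)c + (long)C * n))] / cnt;
          for (int dw = 0; dw < k; ++dw) {
            int wi = wo * stride - pl + dw;
            if (wi < 0 || wi >= W) continue;
            for (int dh = 0; dh < k; ++dh) {
              int hi = ho * stride - pt + dh;
              if (hi >= 0 && hi < H) xc[hi + (long)H * wi] += g;
            }
          }
        }
    }
  return dx;
}
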