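// Low-level tensor kernels for the SE-SPP convolutional classifiers.
// Layout convention: activation tensors are R arrays dim (H, W, C, N),
// column-major; convolution weights are K x Cout matrices with
// K = kh*kw*Cin ordered (ki fastest, then kj, then channel), i.e. the
// column-major flattening of an R array dim (kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int krow = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W) v = xc[hi + (size_t)H * wi];
            col(krow, ho + (size_t)Ho * wo) = v;
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, double* gx, int H, int W, int C,
                   int kh, int kw, int stride, int pad, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int krow = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)H * wi] += col(krow, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericMatrix w,
                            int kh, int kw, int stride, int pad) {
  int H, W, C, N; dims4(x, H, W, C, N);
  if (w.nrow() != kh * kw * C) stop("weight rows do not match kernel * channels");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * C, Cout = w.ncol(), P = Ho * Wo;
  arma::mat wm(w.begin(), K, Cout, false);
  NumericVector out((size_t)P * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat o = col.t() * wm;                     // P x Cout
    std::copy(o.begin(), o.end(), out.begin() + (size_t)P * Cout * n);
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, NumericMatrix w, NumericVector gout,
                   int kh, int kw, int stride, int pad) {
  int H, W, C, N; dims4(x, H, W, C, N);
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * C, Cout = w.ncol(), P = Ho * Wo;
  arma::mat wm(w.begin(), K, Cout, false);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::fill(gx.begin(), gx.end(), 0.0);
  arma::mat gw(K, Cout, arma::fill::zeros);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    arma::mat g(const_cast<double*>(gout.begin()) + (size_t)P * Cout * n, P, Cout, false);
    im2col(xn, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    gw += col * g;                                  // K x Cout
    arma::mat gcol = wm * g.t();                    // K x P
    col2im(gcol, gx.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, Ho, Wo);
  }
  return List::create(_["gx"] = gx, _["gw"] = NumericMatrix(K, Cout, gw.begin()));
}

// [[Rcpp::export]]
List maxpool_fw_cpp(NumericVector x, int k, int stride, int pad) {
  int H, W, C, N; dims4(x, H, W, C, N);
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  size_t M = (size_t)Ho * Wo * C * N;
  NumericVector out(M);
  IntegerVector idx(M);                              // 1-based index into x
  out.attr("dim") = idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf; long bi = -1;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              double v = xc[hi + (size_t)H * wi];
              if (v > best) { best = v; bi = hi + (size_t)H * wi; }
            }
          }
          o = (size_t)(ho + Ho * ((size_t)wo + (size_t)Wo * (c + (size_t)C * n)));
          out[o] = (bi < 0) ? 0.0 : best;
          idx[o] = (bi < 0) ? NA_INTEGER : (int)(base + bi + 1);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bw_cpp(IntegerVector idx, IntegerVector xdim, NumericVector gout) {
  size_t M = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(M);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gout.size(); ++i)
    if (idx[i] != NA_INTEGER) gx[idx[i] - 1] += gout[i];
  return gx;
}

// [[Rcpp::export]]
NumericVector avgpool_fw_cpp(NumericVector x, int k, int stride) {
  int H, W, C, N; dims4(x, H, W, C, N);
  int Ho = (H - k) / stride + 1, Wo = (W - k) / stride + 1;
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  double inv = 1.0 / (k * k);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double s = 0.0;
          for (int kj = 0; kj < k; ++kj)
            for (int ki = 0; ki < k; ++ki)
              s += xc[(ho * stride + ki) + (size_t)H * (wo * stride + kj)];
          o = (size_t)(ho + Ho * ((size_t)wo + (size_t)Wo * (c + (size_t)C * n)));
          out[o] = s * inv;
        }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector avgpool_bw_cpp(IntegerVector xdim, NumericVector gout, int k, int stride) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = (H - k) / stride + 1, Wo = (W - k) / stride + 1;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double g = gout[(size_t)(ho + Ho * ((size_t)wo + (size_t)Wo * (c + (size_t)C * n)))] * inv;
          for (int kj = 0; kj < k; ++kj)
            for (int ki = 0; ki < k; ++ki)
              xc[(ho * stride + ki) + (size_t)H * (wo * stride + kj)] += g;
        }
    }
  return gx;
}

// Spatial pyramid pooling: adaptive max pooling at each pyramid level
// (bins [floor(iH/l), ceil((i+1)H/l)) as in adaptive pooling), flattened
// per level as an (l, l, C) array and concatenated across levels.
// [[Rcpp::export]]
List spp_fw_cpp(NumericVector x, IntegerVector levels) {
  int H, W, C, N; dims4(x, H, W, C, N);
  int F = 0;
  for (int l = 0; l < levels.size(); ++l) F += levels[l] * levels[l];
  F *= C;
  NumericMatrix out(F, N);
  IntegerMatrix idx(F, N);
  for (int n = 0; n < N; ++n) {
    int f = 0;
    for (int li = 0; li < levels.size(); ++li) {
      int L = levels[li];
      if (H < L || W < L) stop("feature map smaller than pyramid level");
      for (int c = 0; c < C; ++c) {
        const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
        size_t base = (size_t)H * W * (c + (size_t)C * n);
        for (int bj = 0; bj < L; ++bj) {
          int ws = (int)std::floor((double)bj * W / L);
          int we = (int)std::ceil((double)(bj + 1) * W / L);
          for (int bi = 0; bi < L; ++bi) {
            int hs = (int)std::floor((double)bi * H / L);
            int he = (int)std::ceil((double)(bi + 1) * H / L);
            double best = R_NegInf; long bidx = 0;
            for (int wi = ws; wi < we; ++wi)
              for (int hi = hs; hi < he; ++hi) {
                double v = xc[hi + (size_t)H * wi];
                if (v > best) { best = v; bidx = hi + (size_t)H * wi; }
              }
            // within-level order (bi, bj, c), levels concatenated
            int pos = f + bi + L * (bj + L * c);
            out(pos, n) = best;
            idx(pos, n) = (int)(base + bidx + 1);
          }
        }
      }
      f += L * L * C;
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector spp_bw_cpp(IntegerMatrix idx, IntegerVector xdim, NumericMatrix gout) {
  size_t M = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(M);
  gx.attr("dim") = xdim;
  for (int n = 0; n < idx.ncol(); ++n)
    for (int f = 0; f < idx.nrow(); ++f)
      gx[idx(f, n) - 1] += gout(f, n);
  return gx;
}
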