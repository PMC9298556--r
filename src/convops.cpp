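// Minibatch convolution and max-pooling primitives for the training engine.
// Arrays follow R's column-major layout with dimensions (height, width,
// channels, batch). Convolutions are an im2col gather plus one BLAS matrix
// product; the im2col patch matrix from the forward pass is returned so the
// backward pass can reuse it. 1x1 unpadded convolutions skip the gather and
// run one small matrix product per sample on views of the input. "Same"
// padding is the symmetric zero padding for odd kernels (floor((k-1)/2)
// leading, the remainder trailing).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector dims_of(const NumericVector& x) {
  return x.attr("dim");
}

// Fill the im2col patch matrix A (K x P*N), K = kh*kw*c, P = oh*ow.
static void im2col(const double* x, int h, int w, int c, int n,
                   int kh, int kw, int oh, int ow,
                   int pad_top, int pad_left, arma::mat& A) {
  const int P = oh * ow;
  const bool padded = pad_top > 0 || pad_left > 0;
  if (padded) A.zeros();
  for (int b = 0; b < n; ++b) {
    const double* xb = x + (size_t)b * h * w * c;
    for (int j = 0; j < ow; ++j) {
      for (int i = 0; i < oh; ++i) {
        double* col = A.colptr((size_t)b * P + (size_t)j * oh + i);
        for (int ci = 0; ci < c; ++ci) {
          const double* xc = xb + (size_t)ci * h * w;
          for (int kj = 0; kj < kw; ++kj) {
            int xj = j + kj - pad_left;
            if (xj < 0 || xj >= w) continue;
            const double* xcol = xc + (size_t)xj * h;
            double* dst = col + (size_t)ci * kh * kw + (size_t)kj * kh;
            for (int ki = 0; ki < kh; ++ki) {
              int xi = i + ki - pad_top;
              if (xi >= 0 && xi < h) dst[ki] = xcol[xi];
            }
          }
        }
      }
    }
  }
}

// Forward pass. Returns the output and, for kernels larger than 1x1, the
// im2col matrix for reuse in the backward pass.
// [[Rcpp::export]]
List conv_fwd(NumericVector x, NumericVector w, NumericVector bias,
              bool same) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  int h = xd[0], wid = xd[1], c = xd[2], n = xd[3];
  int kh = wd[0], kw = wd[1], f = wd[3];
  if (wd[2] != c) stop("channel mismatch between input and kernel");
  int pad_top = same ? (kh - 1) / 2 : 0, pad_left = same ? (kw - 1) / 2 : 0;
  int oh = same ? h : h - kh + 1, ow = same ? wid : wid - kw + 1;
  if (oh < 1 || ow < 1) stop("kernel larger than input");
  const int K = kh * kw * c, P = oh * ow;
  arma::vec bv(bias.begin(), f);

  NumericVector out = alloc4(oh, ow, f, n);
  double* o = out.begin();

  if (kh == 1 && kw == 1) {
    // per-sample (P x c) * (c x f): the input viewed as (P, c) is already
    // column-major contiguous
    arma::mat W(w.begin(), c, f, false, true);
    for (int b = 0; b < n; ++b) {
      arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)b * h * wid * c,
                   P, c, false, true);
      arma::mat Yn(o + (size_t)b * P * f, P, f, false, true);
      Yn = Xn * W;
      Yn.each_row() += bv.t();
    }
    return List::create(_["y"] = out, _["A"] = R_NilValue);
  }

  NumericMatrix A_r(K, (R_xlen_t)P * n);
  arma::mat A(A_r.begin(), K, (size_t)P * n, false, true);
  im2col(x.begin(), h, wid, c, n, kh, kw, oh, ow, pad_top, pad_left, A);
  arma::mat W(w.begin(), K, f, false, true);
  arma::mat Y = W.t() * A;                       // f x P*N
  Y.each_col() += bv;

  for (int b = 0; b < n; ++b)
    for (int fi = 0; fi < f; ++fi) {
      double* dst = o + (size_t)oh * ow * (fi + (size_t)f * b);
      const double* src = Y.memptr() + fi + (size_t)b * P * f;
      for (int p = 0; p < P; ++p) dst[p] = src[(size_t)p * f];
    }
  return List::create(_["y"] = out, _["A"] = A_r);
}

// Backward pass; `A` is the im2col matrix returned by conv_fwd (or NULL for
// a 1x1 kernel). Returns input, weight and bias gradients.
// [[Rcpp::export]]
List conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
              bool same, SEXP A_cache, bool need_dx) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), yd = dims_of(dy);
  int h = xd[0], wid = xd[1], c = xd[2], n = xd[3];
  int kh = wd[0], kw = wd[1], f = wd[3];
  int oh = yd[0], ow = yd[1];
  int pad_top = same ? (kh - 1) / 2 : 0, pad_left = same ? (kw - 1) / 2 : 0;
  const int K = kh * kw * c, P = oh * ow;

  NumericVector dx = alloc4(h, wid, c, n);
  NumericVector dwv = alloc4(kh, kw, c, f);

  if (kh == 1 && kw == 1) {
    arma::mat W(w.begin(), c, f, false, true);
    arma::mat dW(dwv.begin(), c, f, false, true);
    arma::vec db(f, arma::fill::zeros);
    for (int b = 0; b < n; ++b) {
      arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)b * h * wid * c,
                   P, c, false, true);
      arma::mat dYn(const_cast<double*>(dy.begin()) + (size_t)b * P * f,
                    P, f, false, true);
      if (need_dx) {
        arma::mat dXn(dx.begin() + (size_t)b * h * wid * c, P, c, false, true);
        dXn = dYn * W.t();
      }
      dW += Xn.t() * dYn;
      db += arma::sum(dYn, 0).t();
    }
    return List::create(_["dx"] = dx, _["dw"] = dwv,
                        _["db"] = NumericVector(db.begin(), db.end()));
  }

  // dY as (f x P*N)
  arma::mat dY(f, (size_t)P * n);
  const double* dyp = dy.begin();
  for (int b = 0; b < n; ++b)
    for (int fi = 0; fi < f; ++fi) {
      double* dst = dY.memptr() + fi + (size_t)b * P * f;
      const double* src = dyp + (size_t)oh * ow * (fi + (size_t)f * b);
      for (int p = 0; p < P; ++p) dst[(size_t)p * f] = src[p];
    }

  arma::mat A;
  if (A_cache != R_NilValue) {
    NumericMatrix A_r(A_cache);
    A = arma::mat(A_r.begin(), K, (size_t)P * n, false, true);
  } else {
    A.set_size(K, (size_t)P * n);
    im2col(x.begin(), h, wid, c, n, kh, kw, oh, ow, pad_top, pad_left, A);
  }
  arma::mat W(w.begin(), K, f, false, true);

  arma::mat dW = A * dY.t();                     // K x f
  arma::vec db = arma::sum(dY, 1);

  if (need_dx) {
  arma::mat dA = W * dY;                         // K x P*N
  double* dxp = dx.begin();
  for (int b = 0; b < n; ++b) {
    double* xb = dxp + (size_t)b * h * wid * c;
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        const double* col = dA.colptr((size_t)b * P + (size_t)j * oh + i);
        for (int ci = 0; ci < c; ++ci) {
          double* xc = xb + (size_t)ci * h * wid;
          for (int kj = 0; kj < kw; ++kj) {
            int xj = j + kj - pad_left;
            if (xj < 0 || xj >= wid) continue;
            double* xcol = xc + (size_t)xj * h;
            const double* src = col + (size_t)ci * kh * kw + (size_t)kj * kh;
            for (int ki = 0; ki < kh; ++ki) {
              int xi = i + ki - pad_top;
              if (xi >= 0 && xi < h) xcol[xi] += src[ki];
            }
          }
        }
      }
  }
  }

  std::copy(dW.begin(), dW.end(), dwv.begin());
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 stride-2 max pooling; ties resolved to the first element scanned
// (top-left first, column-major within the window).
// [[Rcpp::export]]
List maxpool_fwd(NumericVector x) {
  IntegerVector xd = dims_of(x);
  int h = xd[0], w = xd[1], c = xd[2], n = xd[3];
  int oh = h / 2, ow = w / 2;
  NumericVector y = alloc4(oh, ow, c, n);
  IntegerVector idx(y.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  size_t q = 0;
  for (int b = 0; b < n; ++b)
    for (int ci = 0; ci < c; ++ci) {
      size_t base = ((size_t)b * c + ci) * h * w;
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i, ++q) {
          size_t best = base + (size_t)(2 * j) * h + 2 * i;
          double bv = xp[best];
          size_t cand[3] = {base + (size_t)(2 * j) * h + 2 * i + 1,
                            base + (size_t)(2 * j + 1) * h + 2 * i,
                            base + (size_t)(2 * j + 1) * h + 2 * i + 1};
          for (int t = 0; t < 3; ++t)
            if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
          yp[q] = bv;
          idx[q] = (int)best + 1;    // 1-based for R
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(IntegerVector idx, NumericVector dy,
                          IntegerVector xdim) {
  NumericVector dx = alloc4(xdim[0], xdim[1], xdim[2], xdim[3]);
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  for (R_xlen_t q = 0; q < dy.size(); ++q)
    dxp[idx[q] - 1] += dyp[q];
  return dx;
}

// Elementwise helpers used by the layer graph executor. `inplace_add`
// mutates its first argument, which the executor only calls on gradient
// buffers it allocated itself.

// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin(); double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector y, NumericVector dy) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* yp = y.begin(); const double* dp = dy.begin();
  double* xp = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) xp[i] = yp[i] > 0 ? dp[i] : 0;
  return dx;
}

// [[Rcpp::export]]
NumericVector inplace_add(NumericVector a, NumericVector b) {
  if (a.size() != b.size()) stop("size mismatch in inplace_add");
  double* ap = a.begin(); const double* bp = b.begin();
  for (R_xlen_t i = 0; i < a.size(); ++i) ap[i] += bp[i];
  return a;
}

// Concatenate two (h, w, c, n) arrays along the channel axis.
// [[Rcpp::export]]
NumericVector chan_concat2(NumericVector a, NumericVector b) {
  IntegerVector ad = dims_of(a), bd = dims_of(b);
  int h = ad[0], w = ad[1], ca = ad[2], n = ad[3], cb = bd[2];
  if (bd[0] != h || bd[1] != w || bd[3] != n)
    stop("concat inputs differ in spatial or batch size");
  NumericVector y = alloc4(h, w, ca + cb, n);
  const size_t hw = (size_t)h * w;
  for (int s = 0; s < n; ++s) {
    std::copy(a.begin() + s * hw * ca, a.begin() + (s + 1) * hw * ca,
              y.begin() + s * hw * (ca + cb));
    std::copy(b.begin() + s * hw * cb, b.begin() + (s + 1) * hw * cb,
              y.begin() + s * hw * (ca + cb) + hw * ca);
  }
  return y;
}

// Extract channels [from, from+nc) of an (h, w, c, n) array.
// [[Rcpp::export]]
NumericVector chan_slice(NumericVector x, int from, int nc) {
  IntegerVector xd = dims_of(x);
  int h = xd[0], w = xd[1], c = xd[2], n = xd[3];
  if (from < 1 || from + nc - 1 > c) stop("channel slice out of range");
  NumericVector y = alloc4(h, w, nc, n);
  const size_t hw = (size_t)h * w;
  for (int s = 0; s < n; ++s)
    std::copy(x.begin() + (s * (size_t)c + from - 1) * hw,
              x.begin() + (s * (size_t)c + from - 1 + nc) * hw,
              y.begin() + s * hw * nc);
  return y;
}

// Squared magnitude of the first `keep` rows of a complex matrix -- the
// one-sided power spectrum of a column-per-frame FFT, without the sqrt of
// Mod() or intermediate copies.
// [[Rcpp::export]]
NumericMatrix cplx_power_head(ComplexMatrix z, int keep) {
  int n = z.ncol();
  NumericMatrix out(keep, n);
  for (int j = 0; j < n; ++j) {
    const Rcomplex* zc = &z(0, j);
    double* o = &out(0, j);
    for (int i = 0; i < keep; ++i)
      o[i] = zc[i].r * zc[i].r + zc[i].i * zc[i].i;
  }
  return out;
}
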