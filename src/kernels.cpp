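// Low-level numerical kernels for the network and image utilities.
// Feature maps are R arrays with dim (H, W, C, N), column-major.
// Convolution weights are arrays with dim (k, k, Cin/groups, Cout).

#include <RcppArmadillo.h>
#include <cstring>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int dim4(const NumericVector& x, int i) {
  IntegerVector d = x.attr("dim");
  return d[i];
}

static NumericVector arr4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector iarr4(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// ---------------------------------------------------------------- im2col ---

// Fill P (HW x k*k*Cpg) with patches of channel block [c0, c0+Cpg) of image n.
static void im2col_fill(const double* x, int H, int W, int C, int n,
                        int k, int pad, int c0, int Cpg, arma::mat& P) {
  const double* xn = x + (size_t)H * W * C * n;
  for (int c = 0; c < Cpg; ++c) {
    const double* xc = xn + (size_t)H * W * (c0 + c);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        double* col = P.colptr((size_t)c * k * k + (size_t)kw * k + kh);
        int dh = kh - pad, dw = kw - pad;
        for (int w = 0; w < W; ++w) {
          int ws = w + dw;
          double* dst = col + (size_t)w * H;
          if (ws < 0 || ws >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double* src = xc + (size_t)ws * H;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          for (int h = 0; h < h0; ++h) dst[h] = 0.0;
          if (h1 > h0)
            std::memcpy(dst + h0, src + h0 + dh,
                        (size_t)(h1 - h0) * sizeof(double));
          for (int h = h1; h < H; ++h) dst[h] = 0.0;
        }
      }
    }
  }
}

// Scatter-add dP (HW x k*k*Cpg) back into dx channel block of image n.
static void col2im_add(double* dx, int H, int W, int C, int n,
                       int k, int pad, int c0, int Cpg, const arma::mat& dP) {
  double* xn = dx + (size_t)H * W * C * n;
  for (int c = 0; c < Cpg; ++c) {
    double* xc = xn + (size_t)H * W * (c0 + c);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const double* col = dP.colptr((size_t)c * k * k + (size_t)kw * k + kh);
        int dh = kh - pad, dw = kw - pad;
        for (int w = 0; w < W; ++w) {
          int ws = w + dw;
          if (ws < 0 || ws >= W) continue;
          const double* src = col + (size_t)w * H;
          double* dst = xc + (size_t)ws * H;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          for (int h = h0; h < h1; ++h) dst[h + dh] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w,
                        Nullable<NumericVector> bias, int pad, int groups) {
  int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  IntegerVector wd = w.attr("dim");
  int k = wd[0], Cpg = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("non-square kernel");
  if (C != Cpg * groups) stop("channel/group mismatch");
  int Copg = Cout / groups;
  NumericVector y = arr4(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cpg, Cout,
               false, true);
  if (k == 1 && groups == 1) {
    // pointwise conv: plain GEMM on channel-matrix views, no patch copy
    for (int n = 0; n < N; ++n) {
      arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                   (size_t)H * W, C, false, true);
      arma::mat Yn(y.begin() + (size_t)H * W * Cout * n, (size_t)H * W,
                   Cout, false, true);
      Yn = Xm * Wm;
    }
  } else {
  arma::mat P((size_t)H * W, (size_t)k * k * Cpg);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col_fill(x.begin(), H, W, C, n, k, pad, g * Cpg, Cpg, P);
      arma::mat Yg(y.begin() + (size_t)H * W * (Cout * n + g * Copg),
                   (size_t)H * W, Copg, false, true);
      Yg = P * Wm.cols(g * Copg, (g + 1) * Copg - 1);
    }
  }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c) {
        double bc = b[c];
        double* yc = y.begin() + (size_t)H * W * (c + (size_t)Cout * n);
        for (size_t i = 0; i < (size_t)H * W; ++i) yc[i] += bc;
      }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int pad, int groups, bool has_bias) {
  int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  IntegerVector wd = w.attr("dim");
  int k = wd[0], Cpg = wd[2], Cout = wd[3];
  int Copg = Cout / groups;
  NumericVector dx = arr4(H, W, C, N);
  NumericVector dw = arr4(k, k, Cpg, Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cpg, Cout,
               false, true);
  arma::mat dWm(dw.begin(), (size_t)k * k * Cpg, Cout, false, true);
  if (k == 1 && groups == 1) {
    for (int n = 0; n < N; ++n) {
      arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                   (size_t)H * W, C, false, true);
      arma::mat dYn(const_cast<double*>(dy.begin()) +
                        (size_t)H * W * Cout * n,
                    (size_t)H * W, Cout, false, true);
      arma::mat dXn(dx.begin() + (size_t)H * W * C * n, (size_t)H * W, C,
                    false, true);
      dWm += Xm.t() * dYn;
      dXn = dYn * Wm.t();
    }
  } else {
  arma::mat P((size_t)H * W, (size_t)k * k * Cpg);
  arma::mat dP((size_t)H * W, (size_t)k * k * Cpg);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      arma::mat dYg(const_cast<double*>(dy.begin()) +
                        (size_t)H * W * (Cout * n + g * Copg),
                    (size_t)H * W, Copg, false, true);
      im2col_fill(x.begin(), H, W, C, n, k, pad, g * Cpg, Cpg, P);
      dWm.cols(g * Copg, (g + 1) * Copg - 1) += P.t() * dYg;
      dP = dYg * Wm.cols(g * Copg, (g + 1) * Copg - 1).t();
      col2im_add(dx.begin(), H, W, C, n, k, pad, g * Cpg, Cpg, dP);
    }
  }
  }
  List out = List::create(_["dx"] = dx, _["dw"] = dw);
  if (has_bias) {
    NumericVector db(Cout);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c) {
        const double* yc =
            dy.begin() + (size_t)H * W * (c + (size_t)Cout * n);
        double s = 0;
        for (size_t i = 0; i < (size_t)H * W; ++i) s += yc[i];
        db[c] += s;
      }
    out["db"] = db;
  }
  return out;
}

// ------------------------------------------------- transposed conv 2x2/2 ---

// Weight dim (2, 2, Cin, Cout); output (2H, 2W, Cout, N).
// [[Rcpp::export]]
NumericVector convt2_fw(NumericVector x, NumericVector w,
                        Nullable<NumericVector> bias) {
  int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  IntegerVector wd = w.attr("dim");
  int Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch");
  int H2 = 2 * H, W2 = 2 * W;
  NumericVector y = arr4(H2, W2, Cout, N);
  // Xm: (HW x Cin) view per image; Wm: (Cin x 4*Cout) with (a,b) fastest.
  arma::mat Wm((size_t)4, (size_t)Cin * Cout);
  const double* wp = w.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int j = 0; j < 4; ++j)
        Wm(j, (size_t)ci + (size_t)Cin * co) = wp[j + 4 * (ci + Cin * co)];
  for (int n = 0; n < N; ++n) {
    arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                 (size_t)H * W, C, false, true);
    for (int co = 0; co < Cout; ++co) {
      arma::mat Wco(const_cast<double*>(Wm.colptr((size_t)Cin * co)), 4, Cin,
                    false, true);
      arma::mat B = Xm * Wco.t();  // HW x 4
      double* yc = y.begin() + (size_t)H2 * W2 * (co + (size_t)Cout * n);
      double bc = 0.0;
      if (bias.isNotNull()) bc = NumericVector(bias)[co];
      for (int w0 = 0; w0 < W; ++w0)
        for (int h0 = 0; h0 < H; ++h0) {
          size_t p = (size_t)h0 + (size_t)H * w0;
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a)
              yc[(size_t)(2 * h0 + a) + (size_t)H2 * (2 * w0 + b)] =
                  B(p, a + 2 * b) + bc;
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
List convt2_bw(NumericVector x, NumericVector w, NumericVector dy,
               bool has_bias) {
  int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  IntegerVector wd = w.attr("dim");
  int Cin = wd[2], Cout = wd[3];
  int H2 = 2 * H, W2 = 2 * W;
  NumericVector dx = arr4(H, W, C, N);
  NumericVector dw = arr4(2, 2, Cin, Cout);
  NumericVector db(Cout);
  arma::mat Bg((size_t)H * W, 4);
  for (int n = 0; n < N; ++n) {
    arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                 (size_t)H * W, C, false, true);
    arma::mat dXm(dx.begin() + (size_t)H * W * C * n, (size_t)H * W, C, false,
                  true);
    for (int co = 0; co < Cout; ++co) {
      const double* dyc =
          dy.begin() + (size_t)H2 * W2 * (co + (size_t)Cout * n);
      double s = 0;
      for (int w0 = 0; w0 < W; ++w0)
        for (int h0 = 0; h0 < H; ++h0) {
          size_t p = (size_t)h0 + (size_t)H * w0;
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a) {
              double v = dyc[(size_t)(2 * h0 + a) + (size_t)H2 * (2 * w0 + b)];
              Bg(p, a + 2 * b) = v;
              s += v;
            }
        }
      db[co] += s;
      // dW[a,b,ci,co] += sum_p X[p,ci] * Bg[p,(a,b)]
      arma::mat dWco = Bg.t() * Xm;  // 4 x Cin
      double* dwp = dw.begin() + (size_t)4 * Cin * co;
      for (int ci = 0; ci < Cin; ++ci)
        for (int j = 0; j < 4; ++j) dwp[j + 4 * ci] += dWco(j, ci);
      // dX += Bg * Wco (4 -> Cin)
      arma::mat Wco(4, Cin);
      const double* wp = w.begin() + (size_t)4 * Cin * co;
      for (int ci = 0; ci < Cin; ++ci)
        for (int j = 0; j < 4; ++j) Wco(j, ci) = wp[j + 4 * ci];
      dXm += Bg * Wco;
    }
  }
  List out = List::create(_["dx"] = dx, _["dw"] = dw);
  if (has_bias) out["db"] = db;
  return out;
}

// ------------------------------------------------------------- max pool ---

// [[Rcpp::export]]
List maxpool2_fw(NumericVector x) {
  int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  int H2 = H / 2, W2 = W / 2;
  NumericVector y = arr4(H2, W2, C, N);
  IntegerVector idx = iarr4(H2, W2, C, N);  // linear index into x
  size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)H2 * W2 * (c + (size_t)C * n);
      int* ic = idx.begin() + (size_t)H2 * W2 * (c + (size_t)C * n);
      for (int w = 0; w < W2; ++w)
        for (int h = 0; h < H2; ++h) {
          size_t base = (size_t)2 * h + (size_t)H * 2 * w;
          size_t cand[4] = {base, base + 1, base + H, base + H + 1};
          size_t best = cand[0];
          double bv = xc[cand[0]];
          for (int j = 1; j < 4; ++j)
            if (xc[cand[j]] > bv) { bv = xc[cand[j]]; best = cand[j]; }
          yc[(size_t)h + (size_t)H2 * w] = bv;
          ic[(size_t)h + (size_t)H2 * w] =
              (int)(best + plane * (c + (size_t)C * n));
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw(NumericVector dy, IntegerVector idx,
                          int H, int W) {
  int C = dim4(dy, 2), N = dim4(dy, 3);
  NumericVector dx = arr4(H, W, C, N);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// ------------------------------------------------------ bilinear resize ---

static void lin_weights(int n_out, int n_in, std::vector<int>& i0,
                        std::vector<int>& i1, std::vector<double>& a) {
  i0.resize(n_out); i1.resize(n_out); a.resize(n_out);
  double s = (double)n_in / n_out;
  for (int o = 0; o < n_out; ++o) {
    double src = (o + 0.5) * s - 0.5;
    if (src < 0) src = 0;
    if (src > n_in - 1) src = n_in - 1;
    int lo = (int)std::floor(src);
    int hi = std::min(lo + 1, n_in - 1);
    i0[o] = lo; i1[o] = hi; a[o] = src - lo;
  }
}

// [[Rcpp::export]]
NumericVector resize_bilinear_fw(NumericVector x, int H2, int W2) {
  int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  NumericVector y = arr4(H2, W2, C, N);
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> ah, aw;
  lin_weights(H2, H, h0, h1, ah);
  lin_weights(W2, W, w0, w1, aw);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)H2 * W2 * (c + (size_t)C * n);
      for (int w = 0; w < W2; ++w) {
        const double* cl = xc + (size_t)H * w0[w];
        const double* cr = xc + (size_t)H * w1[w];
        double b = aw[w];
        for (int h = 0; h < H2; ++h) {
          double a = ah[h];
          double top = (1 - b) * cl[h0[h]] + b * cr[h0[h]];
          double bot = (1 - b) * cl[h1[h]] + b * cr[h1[h]];
          yc[(size_t)h + (size_t)H2 * w] = (1 - a) * top + a * bot;
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector resize_bilinear_bw(NumericVector dy, int H, int W) {
  int H2 = dim4(dy, 0), W2 = dim4(dy, 1), C = dim4(dy, 2), N = dim4(dy, 3);
  NumericVector dx = arr4(H, W, C, N);
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> ah, aw;
  lin_weights(H2, H, h0, h1, ah);
  lin_weights(W2, W, w0, w1, aw);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* yc = dy.begin() + (size_t)H2 * W2 * (c + (size_t)C * n);
      for (int w = 0; w < W2; ++w) {
        double b = aw[w];
        for (int h = 0; h < H2; ++h) {
          double a = ah[h], g = yc[(size_t)h + (size_t)H2 * w];
          xc[(size_t)h0[h] + (size_t)H * w0[w]] += (1 - a) * (1 - b) * g;
          xc[(size_t)h0[h] + (size_t)H * w1[w]] += (1 - a) * b * g;
          xc[(size_t)h1[h] + (size_t)H * w0[w]] += a * (1 - b) * g;
          xc[(size_t)h1[h] + (size_t)H * w1[w]] += a * b * g;
        }
      }
    }
  return dx;
}

// ------------------------------------------------------------ batch norm ---

// [[Rcpp::export]]
List bn_fw(NumericVector x, NumericVector gamma, NumericVector beta,
           NumericVector rmean, NumericVector rvar, double momentum,
           bool training, double eps) {
  int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  size_t plane = (size_t)H * W;
  size_t m = plane * N;
  NumericVector y = arr4(H, W, C, N);
  NumericVector mu(C), invstd(C), nrm(C), nrv(C);
  for (int c = 0; c < C; ++c) {
    double mean, var;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + plane * (c + (size_t)C * n);
        for (size_t i = 0; i < plane; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      }
      mean = s / m;
      var = s2 / m - mean * mean;
      if (var < 0) var = 0;
      nrm[c] = (1 - momentum) * rmean[c] + momentum * mean;
      // running variance uses the unbiased estimate
      double ub = m > 1 ? var * (double)m / (m - 1) : var;
      nrv[c] = (1 - momentum) * rvar[c] + momentum * ub;
    } else {
      mean = rmean[c];
      var = rvar[c];
      nrm[c] = rmean[c];
      nrv[c] = rvar[c];
    }
    mu[c] = mean;
    invstd[c] = 1.0 / std::sqrt(var + eps);
    double a = gamma[c] * invstd[c];
    double b = beta[c] - a * mean;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      double* yc = y.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) yc[i] = a * xc[i] + b;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mu, _["invstd"] = invstd,
                      _["rmean"] = nrm, _["rvar"] = nrv);
}

// [[Rcpp::export]]
List bn_bw(NumericVector x, NumericVector gamma, NumericVector mu,
           NumericVector invstd, NumericVector dy) {
  int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  size_t plane = (size_t)H * W;
  double m = (double)plane * N;
  NumericVector dx = arr4(H, W, C, N);
  NumericVector dg(C), db(C);
  for (int c = 0; c < C; ++c) {
    double sum_dy = 0, sum_dy_xhat = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      const double* gyc = dy.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        double xhat = (xc[i] - mu[c]) * invstd[c];
        sum_dy += gyc[i];
        sum_dy_xhat += gyc[i] * xhat;
      }
    }
    dg[c] = sum_dy_xhat;
    db[c] = sum_dy;
    double a = gamma[c] * invstd[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      const double* gyc = dy.begin() + plane * (c + (size_t)C * n);
      double* dxc = dx.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        double xhat = (xc[i] - mu[c]) * invstd[c];
        dxc[i] = a * (gyc[i] - sum_dy / m - xhat * sum_dy_xhat / m);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dg, _["dbeta"] = db);
}

// ------------------------------------- contextual attention aggregation ---

// v: (H, W, d, N) values; att: (H, W, k*k*d, N) window attention weights
// (already normalised over the k*k axis; channel layout j + k*k*c).
// y[h,w,c] = sum_j att[h,w,j+k2*c] * v[h+dh_j, w+dw_j, c]   (zero padded)
// [[Rcpp::export]]
NumericVector cot_agg_fw(NumericVector v, NumericVector att, int k) {
  int H = dim4(v, 0), W = dim4(v, 1), d = dim4(v, 2), N = dim4(v, 3);
  int k2 = k * k, pad = k / 2;
  NumericVector y = arr4(H, W, d, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < d; ++c) {
      const double* vc = v.begin() + (size_t)H * W * (c + (size_t)d * n);
      double* yc = y.begin() + (size_t)H * W * (c + (size_t)d * n);
      for (int j = 0; j < k2; ++j) {
        int dh = j % k - pad, dw = j / k - pad;
        const double* ac =
            att.begin() + (size_t)H * W * (j + k2 * c + (size_t)k2 * d * n);
        for (int w = 0; w < W; ++w) {
          int ws = w + dw;
          if (ws < 0 || ws >= W) continue;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          const double* vcol = vc + (size_t)H * ws;
          const double* acol = ac + (size_t)H * w;
          double* ycol = yc + (size_t)H * w;
          for (int h = h0; h < h1; ++h) ycol[h] += acol[h] * vcol[h + dh];
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
List cot_agg_bw(NumericVector v, NumericVector att, NumericVector dy, int k) {
  int H = dim4(v, 0), W = dim4(v, 1), d = dim4(v, 2), N = dim4(v, 3);
  int k2 = k * k, pad = k / 2;
  NumericVector dv = arr4(H, W, d, N);
  NumericVector datt = arr4(H, W, k2 * d, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < d; ++c) {
      const double* vc = v.begin() + (size_t)H * W * (c + (size_t)d * n);
      double* dvc = dv.begin() + (size_t)H * W * (c + (size_t)d * n);
      const double* gyc = dy.begin() + (size_t)H * W * (c + (size_t)d * n);
      for (int j = 0; j < k2; ++j) {
        int dh = j % k - pad, dw = j / k - pad;
        const double* ac =
            att.begin() + (size_t)H * W * (j + k2 * c + (size_t)k2 * d * n);
        double* dac =
            datt.begin() + (size_t)H * W * (j + k2 * c + (size_t)k2 * d * n);
        for (int w = 0; w < W; ++w) {
          int ws = w + dw;
          if (ws < 0 || ws >= W) continue;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          const double* vcol = vc + (size_t)H * ws;
          double* dvcol = dvc + (size_t)H * ws;
          const double* acol = ac + (size_t)H * w;
          double* dacol = dac + (size_t)H * w;
          const double* gcol = gyc + (size_t)H * w;
          for (int h = h0; h < h1; ++h) {
            dacol[h] += gcol[h] * vcol[h + dh];
            dvcol[h + dh] += gcol[h] * acol[h];
          }
        }
      }
    }
  return List::create(_["dv"] = dv, _["datt"] = datt);
}

// ------------------------------------------- Euclidean distance transform ---

// Felzenszwalb & Huttenlocher exact squared EDT, 1-D pass.
static void edt_1d(const std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& v, std::vector<double>& z) {
  int n = (int)f.size();
  d.assign(n, 0.0);
  int kk = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[kk]] + (double)v[kk] * v[kk])) /
          (2.0 * q - 2.0 * v[kk]);
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = INFINITY;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    double dq = q - v[kk];
    d[q] = dq * dq + f[v[kk]];
  }
}

// Exact Euclidean distance (in pixels) from every cell to the nearest
// nonzero cell of `feature`.  All-zero input returns all-Inf.
// [[Rcpp::export]]
NumericMatrix edt(LogicalMatrix feature) {
  int H = feature.nrow(), W = feature.ncol();
  NumericMatrix D(H, W);
  const double BIG = 1e20;
  // column pass
  std::vector<double> f(H), d(H);
  std::vector<int> v(std::max(H, W) + 1);
  std::vector<double> z(std::max(H, W) + 2);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) f[h] = feature(h, w) ? 0.0 : BIG;
    edt_1d(f, d, v, z);
    for (int h = 0; h < H; ++h) D(h, w) = d[h];
  }
  // row pass
  std::vector<double> fr(W), dr(W);
  for (int h = 0; h < H; ++h) {
    for (int w = 0; w < W; ++w) fr[w] = D(h, w);
    edt_1d(fr, dr, v, z);
    for (int w = 0; w < W; ++w)
      D(h, w) = dr[w] >= BIG ? R_PosInf : std::sqrt(dr[w]);
  }
  return D;
}

// --------------------------------------------------- Zhang-Suen thinning ---

static int ngb(const IntegerMatrix& M, int h, int w, int H, int W) {
  if (h < 0 || h >= H || w < 0 || w >= W) return 0;
  return M(h, w);
}

// number of 8-connected foreground components
static int count_components(const IntegerMatrix& M) {
  int H = M.nrow(), W = M.ncol();
  std::vector<char> seen((size_t)H * W, 0);
  std::vector<int> stack;
  int comps = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      size_t id = (size_t)h + (size_t)H * w;
      if (!M(h, w) || seen[id]) continue;
      ++comps;
      stack.push_back((int)id);
      seen[id] = 1;
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        int ch = cur % H, cw = cur / H;
        for (int dh = -1; dh <= 1; ++dh)
          for (int dw = -1; dw <= 1; ++dw) {
            int nh = ch + dh, nw = cw + dw;
            if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
            size_t nid = (size_t)nh + (size_t)H * nw;
            if (M(nh, nw) && !seen[nid]) {
              seen[nid] = 1;
              stack.push_back((int)nid);
            }
          }
      }
    }
  return comps;
}

// [[Rcpp::export]]
IntegerMatrix thin_mask(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix M(clone(mask));
  bool changed = true;
  std::vector<std::pair<int,int> > del;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int h = 0; h < H; ++h)
        for (int w = 0; w < W; ++w) {
          if (!M(h, w)) continue;
          // neighbours P2..P9 clockwise from north
          int p[8] = {ngb(M, h - 1, w, H, W),     ngb(M, h - 1, w + 1, H, W),
                      ngb(M, h, w + 1, H, W),     ngb(M, h + 1, w + 1, H, W),
                      ngb(M, h + 1, w, H, W),     ngb(M, h + 1, w - 1, H, W),
                      ngb(M, h, w - 1, H, W),     ngb(M, h - 1, w - 1, H, W)};
          int B = 0, A = 0;
          for (int j = 0; j < 8; ++j) {
            B += p[j];
            if (!p[j] && p[(j + 1) % 8]) ++A;
          }
          if (B < 2 || B > 6 || A != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          del.push_back(std::make_pair(h, w));
        }
      for (size_t i = 0; i < del.size(); ++i)
        M(del[i].first, del[i].second) = 0;
      if (!del.empty()) changed = true;
    }
  }
  // staircase clean-up: the two-subcycle scheme can leave 2x2 blocks;
  // delete one connectivity-safe pixel per block until none remain
  bool again = true;
  while (again) {
    again = false;
    for (int h = 0; h + 1 < H && !again; ++h)
      for (int w = 0; w + 1 < W && !again; ++w) {
        if (!(M(h, w) && M(h + 1, w) && M(h, w + 1) && M(h + 1, w + 1)))
          continue;
        int hs[4] = {h, h + 1, h, h + 1};
        int ws[4] = {w, w, w + 1, w + 1};
        for (int j = 0; j < 4; ++j) {
          int hh = hs[j], ww = ws[j];
          int p[8] = {ngb(M, hh - 1, ww, H, W), ngb(M, hh - 1, ww + 1, H, W),
                      ngb(M, hh, ww + 1, H, W), ngb(M, hh + 1, ww + 1, H, W),
                      ngb(M, hh + 1, ww, H, W), ngb(M, hh + 1, ww - 1, H, W),
                      ngb(M, hh, ww - 1, H, W), ngb(M, hh - 1, ww - 1, H, W)};
          int A = 0;
          for (int q = 0; q < 8; ++q)
            if (!p[q] && p[(q + 1) % 8]) ++A;
          if (A == 1) {  // removing this pixel cannot split the curve
            M(hh, ww) = 0;
            again = true;
            break;
          }
        }
        if (!again) {
          // block inside a loop: no locally safe pixel, so fall back to a
          // global check that deleting keeps the component count intact
          int before = count_components(M);
          for (int j = 0; j < 4 && !again; ++j) {
            M(hs[j], ws[j]) = 0;
            if (count_components(M) == before) again = true;
            else M(hs[j], ws[j]) = 1;
          }
          if (!again) return M;  // give up rather than split the skeleton
        }
      }
  }
  return M;
}



// ------------------------------------------------------------------ relu ---

// [[Rcpp::export]]
NumericVector relu_fw(NumericVector x) {
  NumericVector y(clone(x));
  double* p = y.begin();
  for (R_xlen_t i = 0; i < y.size(); ++i)
    if (p[i] < 0) p[i] = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bw(NumericVector x, NumericVector g) {
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* dp = dx.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    dp[i] = xp[i] > 0 ? gp[i] : 0.0;
  return dx;
}

// In-place accumulate: a += b (used for gradient accumulation).
// [[Rcpp::export]]
NumericVector add_into(NumericVector a, NumericVector b) {
  double* ap = a.begin();
  const double* bp = b.begin();
  for (R_xlen_t i = 0; i < a.size(); ++i) ap[i] += bp[i];
  return a;
}

// --------------------------------------- window softmax (k2 positions) ---

// x: (H, W, k2*d, N) with channel layout j + k2*c; softmax over j.
// [[Rcpp::export]]
NumericVector softmax_window_fw(NumericVector x, int k2) {
  int H = dim4(x, 0), W = dim4(x, 1), C = dim4(x, 2), N = dim4(x, 3);
  int d = C / k2;
  NumericVector y = arr4(H, W, C, N);
  size_t plane = (size_t)H * W;
  std::vector<const double*> xs(k2);
  std::vector<double*> ys(k2);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < d; ++c) {
      for (int j = 0; j < k2; ++j) {
        size_t off = plane * ((size_t)j + (size_t)k2 * c +
                              (size_t)C * n);
        xs[j] = x.begin() + off;
        ys[j] = y.begin() + off;
      }
      for (size_t i = 0; i < plane; ++i) {
        double m = xs[0][i];
        for (int j = 1; j < k2; ++j) m = std::max(m, xs[j][i]);
        double s = 0;
        for (int j = 0; j < k2; ++j) {
          // single precision suffices for normalised attention weights
          double e = (double)expf((float)(xs[j][i] - m));
          ys[j][i] = e;
          s += e;
        }
        double inv = 1.0 / s;
        for (int j = 0; j < k2; ++j) ys[j][i] *= inv;
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector softmax_window_bw(NumericVector p, NumericVector g, int k2) {
  int H = dim4(p, 0), W = dim4(p, 1), C = dim4(p, 2), N = dim4(p, 3);
  int d = C / k2;
  NumericVector dx = arr4(H, W, C, N);
  size_t plane = (size_t)H * W;
  std::vector<const double*> ps(k2), gs(k2);
  std::vector<double*> ds(k2);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < d; ++c) {
      for (int j = 0; j < k2; ++j) {
        size_t off = plane * ((size_t)j + (size_t)k2 * c +
                              (size_t)C * n);
        ps[j] = p.begin() + off;
        gs[j] = g.begin() + off;
        ds[j] = dx.begin() + off;
      }
      for (size_t i = 0; i < plane; ++i) {
        double dot = 0;
        for (int j = 0; j < k2; ++j) dot += gs[j][i] * ps[j][i];
        for (int j = 0; j < k2; ++j)
          ds[j][i] = ps[j][i] * (gs[j][i] - dot);
      }
    }
  return dx;
}

// ----------------------------------------------------- disk rasterisation ---

// Accumulate anti-aliased disk coverage into canvas (max-composited).
// xs, ys are 1-based pixel coordinates (rows, cols); rad in pixels.
// [[Rcpp::export]]
NumericMatrix stamp_disks(NumericMatrix canvas, NumericVector ys,
                          NumericVector xs, NumericVector rad) {
  int H = canvas.nrow(), W = canvas.ncol();
  NumericMatrix M(clone(canvas));
  int n = ys.size();
  for (int i = 0; i < n; ++i) {
    double cy = ys[i] - 1.0, cx = xs[i] - 1.0, r = rad[i];
    int h0 = std::max(0, (int)std::floor(cy - r - 1));
    int h1 = std::min(H - 1, (int)std::ceil(cy + r + 1));
    int w0 = std::max(0, (int)std::floor(cx - r - 1));
    int w1 = std::min(W - 1, (int)std::ceil(cx + r + 1));
    for (int w = w0; w <= w1; ++w)
      for (int h = h0; h <= h1; ++h) {
        double dy = h - cy, dx = w - cx;
        double dist = std::sqrt(dy * dy + dx * dx);
        // coverage ~ smooth step over one pixel at the rim
        double cov = r + 0.5 - dist;
        if (cov <= 0) continue;
        if (cov > 1) cov = 1;
        if (cov > M(h, w)) M(h, w) = cov;
      }
  }
  return M;
}
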