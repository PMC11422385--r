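#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays in column-major order with dim (H, W, C, N).
// Convolution weights have dim (kh, kw, Cin/groups, Cout).

static inline int idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + H * (w + W * (c + C * n));
}

// [[Rcpp::export]]
NumericVector nn_conv2d_fwd(NumericVector x, NumericVector wgt,
                            NumericVector bias, int stride, int pad,
                            int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = wgt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cpg = wd[2], Cout = wd[3];
  if (C / groups != cpg) stop("weight/input channel mismatch");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int opg = Cout / groups;
  NumericVector y(Ho * (R_xlen_t)Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const double *px = x.begin(), *pw = wgt.begin(), *pb = bias.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const int g = co / opg;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = pb[co];
          for (int ci = 0; ci < cpg; ++ci) {
            const int cin = g * cpg + ci;
            for (int j = 0; j < kw; ++j) {
              const int iw = wo * stride - pad + j;
              if (iw < 0 || iw >= W) continue;
              for (int i = 0; i < kh; ++i) {
                const int ih = ho * stride - pad + i;
                if (ih < 0 || ih >= H) continue;
                acc += px[idx4(ih, iw, cin, n, H, W, C)] *
                       pw[i + kh * (j + kw * (ci + cpg * co))];
              }
            }
          }
          py[idx4(ho, wo, co, n, Ho, Wo, Cout)] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv2d_bwd(NumericVector x, NumericVector wgt, NumericVector gy,
                   int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = wgt.attr("dim");
  IntegerVector yd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cpg = wd[2], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int opg = Cout / groups;
  NumericVector gx(x.size()), gw(wgt.size()), gb(Cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  const double *px = x.begin(), *pw = wgt.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const int g = co / opg;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const double gv = pg[idx4(ho, wo, co, n, Ho, Wo, Cout)];
          if (gv == 0.0) continue;
          pgb[co] += gv;
          for (int ci = 0; ci < cpg; ++ci) {
            const int cin = g * cpg + ci;
            for (int j = 0; j < kw; ++j) {
              const int iw = wo * stride - pad + j;
              if (iw < 0 || iw >= W) continue;
              for (int i = 0; i < kh; ++i) {
                const int ih = ho * stride - pad + i;
                if (ih < 0 || ih >= H) continue;
                const int xi = idx4(ih, iw, cin, n, H, W, C);
                const int wi = i + kh * (j + kw * (ci + cpg * co));
                pgx[xi] += gv * pw[wi];
                pgw[wi] += gv * px[xi];
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List nn_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y(Ho * (R_xlen_t)Wo * C * N);
  IntegerVector arg(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = arg.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          int bi = -1;
          for (int j = 0; j < k; ++j) {
            const int iw = wo * stride - pad + j;
            if (iw < 0 || iw >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int ih = ho * stride - pad + i;
              if (ih < 0 || ih >= H) continue;
              const int xi = idx4(ih, iw, c, n, H, W, C);
              if (px[xi] > best) { best = px[xi]; bi = xi; }
            }
          }
          const int yi = idx4(ho, wo, c, n, Ho, Wo, C);
          py[yi] = best;
          pa[yi] = bi;
        }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bwd(NumericVector gy, IntegerVector arg,
                             IntegerVector xdim) {
  R_xlen_t nx = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(nx);
  gx.attr("dim") = xdim;
  double *pgx = gx.begin();
  const double *pg = gy.begin();
  const int *pa = arg.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    if (pa[i] >= 0) pgx[pa[i]] += pg[i];
  return gx;
}
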