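#include <Rcpp.h>
using namespace Rcpp;

// Convolution / pooling kernels for the small CNNs.
//
// Array layout is R column-major throughout:
//   signals      x : [H, W, C, N]   (rows, time, channels, batch)
//   conv kernels k : [kh, kw, C, F]
//   conv output  y : [Ho, Wo, F, N] with Ho = H-kh+1, Wo = W-kw+1 ("valid")
// Convolution is implemented as cross-correlation, the deep-learning
// convention. Max-pooling acts along the time (W) axis only, width = stride.

static inline R_xlen_t idx4(int a, int b, int c, int d, int A, int B, int C) {
  return a + (R_xlen_t)A * (b + (R_xlen_t)B * (c + (R_xlen_t)C * d));
}

// [[Rcpp::export]]
NumericVector conv2dForwardC(NumericVector x, NumericVector k,
                             NumericVector bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector kd = k.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = kd[0], kw = kd[1], F = kd[3];
  if (kd[2] != C) stop("kernel channel count does not match input");
  if (kh > H || kw > W) stop("kernel larger than input extent");
  const int Ho = H - kh + 1, Wo = W - kw + 1;

  NumericVector y((R_xlen_t)Ho * Wo * F * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  const double *xp = x.begin(), *kp = k.begin(), *bp = bias.begin();
  double *yp = y.begin();

  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = bp[f];
          for (int c = 0; c < C; ++c)
            for (int kwi = 0; kwi < kw; ++kwi) {
              const double *xcol = xp + idx4(ho, wo + kwi, c, n, H, W, C);
              const double *kcol = kp + idx4(0, kwi, c, f, kh, kw, C);
              for (int khi = 0; khi < kh; ++khi)
                acc += xcol[khi] * kcol[khi];
            }
          yp[idx4(ho, wo, f, n, Ho, Wo, F)] = acc;
        }
  return y;
}

// [[Rcpp::export]]
List conv2dBackwardC(NumericVector x, NumericVector k, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector kd = k.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = kd[0], kw = kd[1], F = kd[3];
  const int Ho = H - kh + 1, Wo = W - kw + 1;

  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dk((R_xlen_t)kh * kw * C * F);
  dk.attr("dim") = kd;
  NumericVector db(F);

  const double *xp = x.begin(), *kp = k.begin(), *dyp = dy.begin();
  double *dxp = dx.begin(), *dkp = dk.begin(), *dbp = db.begin();

  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = dyp[idx4(ho, wo, f, n, Ho, Wo, F)];
          if (g == 0.0) continue;
          dbp[f] += g;
          for (int c = 0; c < C; ++c)
            for (int kwi = 0; kwi < kw; ++kwi) {
              const double *xcol = xp + idx4(ho, wo + kwi, c, n, H, W, C);
              const double *kcol = kp + idx4(0, kwi, c, f, kh, kw, C);
              double *dxcol = dxp + idx4(ho, wo + kwi, c, n, H, W, C);
              double *dkcol = dkp + idx4(0, kwi, c, f, kh, kw, C);
              for (int khi = 0; khi < kh; ++khi) {
                dkcol[khi] += xcol[khi] * g;
                dxcol[khi] += kcol[khi] * g;
              }
            }
        }
  return List::create(Named("dx") = dx, Named("dk") = dk, Named("db") = db);
}

// Max-pool along the time axis, non-overlapping windows of width `pool`
// (trailing remainder discarded). idx records the winning time index
// (0-based, into the input) for the backward pass.
// [[Rcpp::export]]
List maxpoolForwardC(NumericVector x, int pool) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Wo = W / pool;
  if (Wo < 1) stop("pooling window larger than time extent");

  NumericVector y((R_xlen_t)H * Wo * C * N);
  IntegerVector id((R_xlen_t)H * Wo * C * N);
  y.attr("dim") = IntegerVector::create(H, Wo, C, N);
  id.attr("dim") = IntegerVector::create(H, Wo, C, N);
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ip = id.begin();

  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int h = 0; h < H; ++h) {
          int best = wo * pool;
          double bv = xp[idx4(h, best, c, n, H, W, C)];
          for (int p = 1; p < pool; ++p) {
            const double v = xp[idx4(h, wo * pool + p, c, n, H, W, C)];
            if (v > bv) { bv = v; best = wo * pool + p; }
          }
          yp[idx4(h, wo, c, n, H, Wo, C)] = bv;
          ip[idx4(h, wo, c, n, H, Wo, C)] = best;
        }
  return List::create(Named("y") = y, Named("idx") = id);
}

// [[Rcpp::export]]
NumericVector maxpoolBackwardC(IntegerVector idx, NumericVector dy, int W) {
  IntegerVector yd = dy.attr("dim");
  const int H = yd[0], Wo = yd[1], C = yd[2], N = yd[3];

  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *dyp = dy.begin();
  const int *ip = idx.begin();
  double *dxp = dx.begin();

  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int h = 0; h < H; ++h) {
          const R_xlen_t o = idx4(h, wo, c, n, H, Wo, C);
          dxp[idx4(h, ip[o], c, n, H, W, C)] += dyp[o];
        }
  return dx;
}
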