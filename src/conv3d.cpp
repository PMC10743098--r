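// 3D convolution primitives for the volumetric regression network.
// Feature maps are R arrays with dim (D, H, W, C), column-major, so each
// channel is a contiguous spatial block. Weights have dim (k, k, k, Cin, Cout),
// so the natural column-major flattening gives a (k^3*Cin) x Cout matrix whose
// row order matches the im2col column order used below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4D array (D, H, W, C)");
  return d;
}

// Gather im2col matrix: rows index output voxels (d fastest), columns index
// (kd, kh, kw, cin). Zero padding outside the grid.
static arma::mat im2col(const double* x, int D, int H, int W, int C,
                        int k, int stride, int pad,
                        int Do, int Ho, int Wo) {
  const arma::uword nout = (arma::uword)Do * Ho * Wo;
  arma::mat col(nout, (arma::uword)k * k * k * C, arma::fill::zeros);
  const long DH = (long)D * H;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (long)c * DH * W;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          arma::uword colIdx = (arma::uword)kd + k * (kh + (long)k * (kw + (long)k * c));
          double* dst = col.colptr(colIdx);
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              for (int dn = 0; dn < Do; ++dn) {
                int di = dn * stride - pad + kd;
                if (di < 0 || di >= D) continue;
                dst[dn + (long)Do * (ho + (long)Ho * wo)] =
                  xc[di + (long)D * hi + DH * wi];
              }
            }
          }
        }
  }
  return col;
}

// Scatter-add the im2col adjoint back onto the input grid.
static void col2im(const arma::mat& col, double* gx, int D, int H, int W, int C,
                   int k, int stride, int pad, int Do, int Ho, int Wo) {
  const long DH = (long)D * H;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (long)c * DH * W;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          arma::uword colIdx = (arma::uword)kd + k * (kh + (long)k * (kw + (long)k * c));
          const double* src = col.colptr(colIdx);
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              for (int dn = 0; dn < Do; ++dn) {
                int di = dn * stride - pad + kd;
                if (di < 0 || di >= D) continue;
                gc[di + (long)D * hi + DH * wi] +=
                  src[dn + (long)Do * (ho + (long)Ho * wo)];
              }
            }
          }
        }
  }
}

static inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 5) stop("weights must have dim (k, k, k, Cin, Cout)");
  int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  int k = wd[0], Cin = wd[3], Cout = wd[4];
  if (Cin != C) stop("channel mismatch between input and weights");
  int Do = out_extent(D, k, stride, pad), Ho = out_extent(H, k, stride, pad),
      Wo = out_extent(W, k, stride, pad);
  arma::mat col = im2col(x.begin(), D, H, W, C, k, stride, pad, Do, Ho, Wo);
  arma::mat Wm(w.begin(), (arma::uword)k * k * k * Cin, Cout, false, true);
  arma::mat Y = col * Wm;
  Y.each_row() += arma::rowvec(b.begin(), Cout, false, true);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout);
  return out;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad) {
  IntegerVector xd = dims4(x), gd = dims4(gy);
  IntegerVector wd = w.attr("dim");
  int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  int k = wd[0], Cin = wd[3], Cout = wd[4];
  int Do = gd[0], Ho = gd[1], Wo = gd[2];
  arma::mat col = im2col(x.begin(), D, H, W, C, k, stride, pad, Do, Ho, Wo);
  arma::mat G(gy.begin(), (arma::uword)Do * Ho * Wo, Cout, false, true);
  arma::mat Wm(w.begin(), (arma::uword)k * k * k * Cin, Cout, false, true);

  arma::mat gw = col.t() * G;
  arma::rowvec gb = arma::sum(G, 0);
  arma::mat gcol = G * Wm.t();

  NumericVector gx(x.size());
  std::fill(gx.begin(), gx.end(), 0.0);
  col2im(gcol, gx.begin(), D, H, W, C, k, stride, pad, Do, Ho, Wo);
  gx.attr("dim") = xd;

  NumericVector gwv(gw.begin(), gw.end());
  gwv.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// Non-overlapping transposed convolution: kernel size == stride == k.
// Each input voxel paints a k^3 block of the output.
// [[Rcpp::export(name = ".convt3d_fwd")]]
NumericVector convt3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  int k = wd[0], Cin = wd[3], Cout = wd[4];
  if (Cin != C) stop("channel mismatch between input and weights");
  int Do = D * k, Ho = H * k, Wo = W * k;
  const arma::uword nin = (arma::uword)D * H * W;
  arma::mat X(x.begin(), nin, C, false, true);

  NumericVector y((long)Do * Ho * Wo * Cout);
  double* yp = y.begin();
  const long DoHo = (long)Do * Ho;
  // one GEMM per kernel offset
  for (int kw = 0; kw < k; ++kw)
    for (int kh = 0; kh < k; ++kh)
      for (int kd = 0; kd < k; ++kd) {
        arma::mat Wsub(Cin, Cout);
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co)
            Wsub(ci, co) = w[kd + (long)k * kh + (long)k * k * kw +
                             (long)k * k * k * (ci + (long)Cin * co)];
        arma::mat Y = X * Wsub;  // nin x Cout
        for (int co = 0; co < Cout; ++co) {
          const double* src = Y.colptr(co);
          double* yc = yp + (long)co * DoHo * Wo;
          for (int wi = 0; wi < W; ++wi)
            for (int hi = 0; hi < H; ++hi)
              for (int di = 0; di < D; ++di)
                yc[(di * k + kd) + (long)Do * (hi * k + kh) + DoHo * (wi * k + kw)] =
                  src[di + (long)D * hi + (long)D * H * wi];
        }
      }
  // bias
  for (int co = 0; co < Cout; ++co) {
    double* yc = yp + (long)co * DoHo * Wo;
    double bv = b[co];
    if (bv != 0.0) for (long i = 0; i < DoHo * Wo; ++i) yc[i] += bv;
  }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout);
  return y;
}

// [[Rcpp::export(name = ".convt3d_bwd")]]
List convt3d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  int k = wd[0], Cin = wd[3], Cout = wd[4];
  int Do = D * k, Ho = H * k, Wo = W * k;
  const arma::uword nin = (arma::uword)D * H * W;
  const long DoHo = (long)Do * Ho;
  arma::mat X(x.begin(), nin, C, false, true);
  const double* gp = gy.begin();

  arma::mat GX(nin, Cin, arma::fill::zeros);
  NumericVector gw(w.size());
  std::fill(gw.begin(), gw.end(), 0.0);
  NumericVector gb(Cout);

  for (int co = 0; co < Cout; ++co) {
    const double* gc = gp + (long)co * DoHo * Wo;
    double s = 0.0;
    for (long i = 0; i < DoHo * Wo; ++i) s += gc[i];
    gb[co] = s;
  }

  for (int kw = 0; kw < k; ++kw)
    for (int kh = 0; kh < k; ++kh)
      for (int kd = 0; kd < k; ++kd) {
        arma::mat Gsub(nin, Cout);
        for (int co = 0; co < Cout; ++co) {
          const double* gc = gp + (long)co * DoHo * Wo;
          double* dst = Gsub.colptr(co);
          for (int wi = 0; wi < W; ++wi)
            for (int hi = 0; hi < H; ++hi)
              for (int di = 0; di < D; ++di)
                dst[di + (long)D * hi + (long)D * H * wi] =
                  gc[(di * k + kd) + (long)Do * (hi * k + kh) + DoHo * (wi * k + kw)];
        }
        arma::mat Wsub(Cin, Cout);
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co)
            Wsub(ci, co) = w[kd + (long)k * kh + (long)k * k * kw +
                             (long)k * k * k * (ci + (long)Cin * co)];
        GX += Gsub * Wsub.t();
        arma::mat gWsub = X.t() * Gsub;  // Cin x Cout
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co)
            gw[kd + (long)k * kh + (long)k * k * kw +
               (long)k * k * k * (ci + (long)Cin * co)] += gWsub(ci, co);
      }

  NumericVector gx(GX.begin(), GX.end());
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
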