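// Compiled kernels for the convolutional backbone: 3x3 "same" convolution
// (forward and backward, via im2col packing and BLAS dgemm) and 2x2/stride-2
// max pooling with deterministic first-maximum gradient routing.  Arrays are
// column-major H x W x C x N, matching R.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cstring>
using namespace Rcpp;

// Packs x (H,W,Cin,N) into an (H*W*N) x (9*Cin) matrix whose column
// (dy+1) + 3*(dx+1) + 9*ci holds the (dy,dx)-shifted plane of channel ci;
// out-of-image entries stay zero ("same" padding).  Row order is (h, w, n).
static void im2col3x3(const double* x, int H, int W, int Cin, int N,
                      double* cols) {
  const size_t plane = (size_t)H * W;
  const size_t R = plane * N;
  for (int ci = 0; ci < Cin; ++ci) {
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        double* col = cols + (size_t)((dy + 1) + 3 * (dx + 1) + 9 * ci) * R;
        const int w0 = std::max(0, -dx), w1 = std::min(W, W - dx);
        const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
        for (int n = 0; n < N; ++n) {
          const double* xp = x + ((size_t)n * Cin + ci) * plane;
          double* dst = col + (size_t)n * plane;
          for (int w = w0; w < w1; ++w) {
            std::memcpy(dst + (size_t)w * H + h0,
                        xp + (size_t)(w + dx) * H + h0 + dy,
                        (size_t)(h1 - h0) * sizeof(double));
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List conv3x3_fwd_cpp(NumericVector x, IntegerVector xd, NumericVector k,
                     int cout, NumericVector b) {
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int R = H * W * N, Kc = 9 * Cin;
  const size_t plane = (size_t)H * W;
  NumericVector cols((R_xlen_t)R * Kc);
  im2col3x3(x.begin(), H, W, Cin, N, cols.begin());
  NumericVector tmp((R_xlen_t)R * cout);
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &R, &cout, &Kc, &one, cols.begin(), &R,
                  k.begin(), &Kc, &zero, tmp.begin(), &R FCONE FCONE);
  // permute (h,w,n) x cout -> (H,W,cout,N) and add the bias
  NumericVector out((R_xlen_t)plane * cout * N);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < cout; ++co) {
      const double* src = tmp.begin() + (size_t)co * R + (size_t)n * plane;
      double* dst = out.begin() + ((size_t)n * cout + co) * plane;
      const double bias = b[co];
      for (size_t i = 0; i < plane; ++i) dst[i] = src[i] + bias;
    }
  }
  return List::create(_["out"] = out, _["cols"] = cols);
}

// [[Rcpp::export]]
List conv3x3_bwd_cpp(NumericVector dout, NumericVector cols, IntegerVector xd,
                     NumericVector k, int cout) {
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int R = H * W * N, Kc = 9 * Cin;
  const size_t plane = (size_t)H * W;
  NumericVector dmat((R_xlen_t)R * cout), db(cout);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < cout; ++co) {
      std::memcpy(dmat.begin() + (size_t)co * R + (size_t)n * plane,
                  dout.begin() + ((size_t)n * cout + co) * plane,
                  plane * sizeof(double));
    }
  }
  for (int co = 0; co < cout; ++co) {
    const double* c0 = dmat.begin() + (size_t)co * R;
    double acc = 0.0;
    for (int i = 0; i < R; ++i) acc += c0[i];
    db[co] = acc;
  }
  const double one = 1.0, zero = 0.0;
  NumericVector dk((R_xlen_t)Kc * cout);
  F77_CALL(dgemm)("T", "N", &Kc, &cout, &R, &one, cols.begin(), &R,
                  dmat.begin(), &R, &zero, dk.begin(), &Kc FCONE FCONE);
  NumericVector dcols((R_xlen_t)R * Kc);
  F77_CALL(dgemm)("N", "T", &R, &Kc, &cout, &one, dmat.begin(), &R,
                  k.begin(), &Kc, &zero, dcols.begin(), &R FCONE FCONE);
  // col2im: scatter-add the unpacked gradients back onto the input grid
  NumericVector dx_((R_xlen_t)plane * Cin * N);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const double* col =
          dcols.begin() + (size_t)((dy + 1) + 3 * (dx + 1) + 9 * ci) * (size_t)R;
        const int w0 = std::max(0, -dx), w1 = std::min(W, W - dx);
        const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
        for (int n = 0; n < N; ++n) {
          double* gx = dx_.begin() + ((size_t)n * Cin + ci) * plane;
          const double* src = col + (size_t)n * plane;
          for (int w = w0; w < w1; ++w) {
            double* g = gx + (size_t)(w + dx) * H + dy;
            const double* s = src + (size_t)w * H;
            for (int h = h0; h < h1; ++h) g[h] += s[h];
          }
        }
      }
    }
  }
  return List::create(_["dK"] = dk, _["db"] = db, _["dX"] = dx_);
}

// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x, IntegerVector xd) {
  const int H = xd[0], W = xd[1];
  const int planes = xd[2] * xd[3];
  const int Ho = H / 2, Wo = W / 2;
  const size_t sP = (size_t)H * W, oP = (size_t)Ho * Wo;
  NumericVector out((R_xlen_t)(oP * planes));
  IntegerVector arg((R_xlen_t)(oP * planes));
  // candidate order within each 2x2 window: (0,0), (1,0), (0,1), (1,1);
  // strict comparison keeps the first maximum under ties.
  const int dr[4] = {0, 1, 0, 1}, dc_[4] = {0, 0, 1, 1};
  for (int p = 0; p < planes; ++p) {
    const double* xp = x.begin() + (size_t)p * sP;
    double* op = out.begin() + (size_t)p * oP;
    int* ap = arg.begin() + (size_t)p * oP;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = R_NegInf;
        int bi = 0;
        for (int c = 0; c < 4; ++c) {
          const double v = xp[(size_t)(2 * wo + dc_[c]) * H + 2 * ho + dr[c]];
          if (v > best) { best = v; bi = c; }
        }
        op[(size_t)wo * Ho + ho] = best;
        ap[(size_t)wo * Ho + ho] = bi;
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dout, IntegerVector arg,
                               IntegerVector xd) {
  const int H = xd[0], W = xd[1];
  const int planes = xd[2] * xd[3];
  const int Ho = H / 2, Wo = W / 2;
  const size_t sP = (size_t)H * W, oP = (size_t)Ho * Wo;
  NumericVector dx_((R_xlen_t)(sP * planes));
  const int dr[4] = {0, 1, 0, 1}, dc_[4] = {0, 0, 1, 1};
  for (int p = 0; p < planes; ++p) {
    const double* dp = dout.begin() + (size_t)p * oP;
    const int* ap = arg.begin() + (size_t)p * oP;
    double* gx = dx_.begin() + (size_t)p * sP;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int c = ap[(size_t)wo * Ho + ho];
        gx[(size_t)(2 * wo + dc_[c]) * H + 2 * ho + dr[c]] =
          dp[(size_t)wo * Ho + ho];
      }
    }
  }
  return dx_;
}
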