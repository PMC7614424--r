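// Minimal dense-network kernels: 3x3 same-padding convolution and 2x2
// max-pooling, forward and backward, batched over the trailing dimension.
// Arrays follow R's column-major layout with dim (H, W, C, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for a 3x3 kernel with zero padding 1, stride 1.
// x points at one sample (H x W x C); returns (H*W) x (9*C).
// Column r = c*9 + dj*3 + di holds x shifted by (di-1, dj-1).
static arma::mat im2col3(const double* x, int H, int W, int C) {
  arma::mat M(static_cast<size_t>(H) * W, static_cast<size_t>(9) * C,
              arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + static_cast<size_t>(c) * H * W;
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int r = c * 9 + dj * 3 + di;
        const int oi = di - 1, oj = dj - 1;
        const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
        const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
        double* mcol = M.colptr(r);
        for (int j = j0; j < j1; ++j) {
          const double* src = xc + static_cast<size_t>(j + oj) * H + (i0 + oi);
          double* dst = mcol + static_cast<size_t>(j) * H + i0;
          std::copy(src, src + (i1 - i0), dst);
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector conv3x3_forward(NumericVector x, NumericMatrix Wm,
                              NumericVector b) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int F = Wm.ncol();
  if (Wm.nrow() != 9 * C) stop("weight matrix rows must equal 9 * channels");
  const arma::mat Wa(Wm.begin(), Wm.nrow(), F, false);
  arma::rowvec ba(b.begin(), F);
  NumericVector y(static_cast<R_xlen_t>(H) * W * F * N);
  y.attr("dim") = IntegerVector::create(H, W, F, N);
  const size_t in_stride = static_cast<size_t>(H) * W * C;
  const size_t out_stride = static_cast<size_t>(H) * W * F;
  for (int n = 0; n < N; ++n) {
    arma::mat M = im2col3(x.begin() + n * in_stride, H, W, C);
    arma::mat Y = M * Wa;
    Y.each_row() += ba;
    std::copy(Y.begin(), Y.end(), y.begin() + n * out_stride);
  }
  return y;
}

// [[Rcpp::export]]
List conv3x3_backward(NumericVector x, NumericMatrix Wm, NumericVector dy,
                      bool need_dx, bool need_dw) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int F = Wm.ncol();
  const arma::mat Wa(Wm.begin(), Wm.nrow(), F, false);
  arma::mat dW(9 * C, F, arma::fill::zeros);
  arma::rowvec db(F, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector(static_cast<R_xlen_t>(H) * W * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  const size_t in_stride = static_cast<size_t>(H) * W * C;
  const size_t out_stride = static_cast<size_t>(H) * W * F;
  for (int n = 0; n < N; ++n) {
    const arma::mat dYn(const_cast<double*>(dy.begin()) + n * out_stride,
                        static_cast<size_t>(H) * W, F, false, true);
    if (need_dw) {
      arma::mat M = im2col3(x.begin() + n * in_stride, H, W, C);
      dW += M.t() * dYn;
      db += arma::sum(dYn, 0);
    }
    if (need_dx) {
      arma::mat G = dYn * Wa.t();  // (H*W) x (9*C)
      double* dxn = dx.begin() + n * in_stride;
      for (int c = 0; c < C; ++c) {
        double* dxc = dxn + static_cast<size_t>(c) * H * W;
        for (int dj = 0; dj < 3; ++dj) {
          for (int di = 0; di < 3; ++di) {
            const int r = c * 9 + dj * 3 + di;
            const int oi = di - 1, oj = dj - 1;
            const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
            const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
            const double* gcol = G.colptr(r);
            for (int j = j0; j < j1; ++j) {
              const double* src = gcol + static_cast<size_t>(j) * H + i0;
              double* dst = dxc + static_cast<size_t>(j + oj) * H + (i0 + oi);
              for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
            }
          }
        }
      }
    }
  }
  List out = List::create(_["dW"] = wrap(dW), _["db"] = wrap(arma::vec(db.t())));
  if (need_dx) out["dx"] = dx;
  return out;
}

// 2x2 max pool, stride 2; odd trailing rows/columns are dropped.
// Returns pooled values and the 0-based argmax index within each (H, W)
// plane, for the backward scatter.
// [[Rcpp::export]]
List maxpool2_forward(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;
  if (Ho < 1 || Wo < 1) stop("input too small to pool");
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const size_t in_plane = static_cast<size_t>(H) * W;
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (static_cast<size_t>(n) * C + c) * in_plane;
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          const int i = 2 * io, j = 2 * jo;
          int best = i + j * H;
          double bv = xp[best];
          const int cand[3] = {i + 1 + j * H, i + (j + 1) * H,
                               i + 1 + (j + 1) * H};
          for (int k = 0; k < 3; ++k) {
            if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
          }
          y[o] = bv;
          idx[o] = best;
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_backward(NumericVector dy, IntegerVector idx,
                                IntegerVector in_dim) {
  const int H = in_dim[0], W = in_dim[1], C = in_dim[2], N = in_dim[3];
  IntegerVector d = dy.attr("dim");
  const int Ho = d[0], Wo = d[1];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = in_dim;
  const size_t in_plane = static_cast<size_t>(H) * W;
  const size_t out_plane = static_cast<size_t>(Ho) * Wo;
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* dxp = dx.begin() + (static_cast<size_t>(n) * C + c) * in_plane;
      for (size_t k = 0; k < out_plane; ++k, ++o) dxp[idx[o]] += dy[o];
    }
  }
  return dx;
}
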