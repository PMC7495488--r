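// Minimal CNN primitives for single-channel image denoisers.
// Layout: images/feature maps are arma::cube (H x W x C); a convolution
// layer's weights are a dense matrix F x (K*K*C) whose column ordering
// matches the (channel, kj, ki) loop order below, plus a bias vector of
// length F. All convolutions are 'same'-size with zero padding and odd K.
// The patch matrix is kept transposed (HW x K*K*C) so that both the fill
// and the GEMMs run down contiguous columns.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

static mat im2col_t(const cube& x, const int K) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, r = K / 2;
  mat out((uword)H * (uword)W, K * K * C, fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    const mat& s = x.slice(c);
    for (int kj = -r; kj <= r; ++kj) {
      for (int ki = -r; ki <= r; ++ki) {
        mat sh(H, W, fill::zeros);
        const int i0 = std::max(0, -ki), i1 = std::min(H, H - ki);
        const int j0 = std::max(0, -kj), j1 = std::min(W, W - kj);
        if (i1 > i0 && j1 > j0)
          sh.submat(i0, j0, i1 - 1, j1 - 1) =
            s.submat(i0 + ki, j0 + kj, i1 - 1 + ki, j1 - 1 + kj);
        out.col(col++) = vectorise(sh);
      }
    }
  }
  return out;
}

static void col2im_add_t(cube& dx, const mat& colsT, const int K) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices, r = K / 2;
  int col = 0;
  for (int c = 0; c < C; ++c) {
    for (int kj = -r; kj <= r; ++kj) {
      for (int ki = -r; ki <= r; ++ki) {
        const mat g = reshape(colsT.col(col++), H, W);
        const int i0 = std::max(0, -ki), i1 = std::min(H, H - ki);
        const int j0 = std::max(0, -kj), j1 = std::min(W, W - kj);
        if (i1 > i0 && j1 > j0)
          dx.slice(c).submat(i0 + ki, j0 + kj, i1 - 1 + ki, j1 - 1 + kj) +=
            g.submat(i0, j0, i1 - 1, j1 - 1);
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, const int K) {
  const int H = x.n_rows, W = x.n_cols, F = w.n_rows;
  mat yT = im2col_t(x, K) * w.t();      // HW x F
  yT.each_row() += b.t();
  cube out(H, W, F);
  for (int f = 0; f < F; ++f) out.slice(f) = reshape(yT.col(f), H, W);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& w,
                      const arma::cube& dy, const int K) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, F = w.n_rows;
  mat colsT = im2col_t(x, K);
  mat dyT((uword)H * (uword)W, F);
  for (int f = 0; f < F; ++f) dyT.col(f) = vectorise(dy.slice(f));
  mat dW = (colsT.t() * dyT).t();       // F x K*K*C
  vec db = sum(dyT, 0).t();
  mat dcolsT = dyT * w;                 // HW x K*K*C
  cube dx(H, W, C, fill::zeros);
  col2im_add_t(dx, dcolsT, K);
  return List::create(_["dx"] = dx, _["dw"] = dW, _["db"] = db);
}

// 2x2 max pooling (stride 2). Input dims must be even.
// [[Rcpp::export]]
Rcpp::List maxpool2_fwd(const arma::cube& x) {
  const int h = x.n_rows / 2, w2 = x.n_cols / 2, C = x.n_slices;
  cube y(h, w2, C);
  icube idx(h, w2, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w2; ++j)
      for (int i = 0; i < h; ++i) {
        double best = x(2 * i, 2 * j, c);
        int bi = 0;
        double v = x(2 * i + 1, 2 * j, c);
        if (v > best) { best = v; bi = 1; }
        v = x(2 * i, 2 * j + 1, c);
        if (v > best) { best = v; bi = 2; }
        v = x(2 * i + 1, 2 * j + 1, c);
        if (v > best) { best = v; bi = 3; }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::cube& dy, const arma::icube& idx) {
  const int h = dy.n_rows, w2 = dy.n_cols, C = dy.n_slices;
  cube dx(2 * h, 2 * w2, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w2; ++j)
      for (int i = 0; i < h; ++i) {
        const int bi = idx(i, j, c);
        dx(2 * i + (bi & 1), 2 * j + (bi >> 1), c) = dy(i, j, c);
      }
  return dx;
}

// Nearest-neighbour 2x upsampling and its adjoint.
// [[Rcpp::export]]
arma::cube upsample2_fwd(const arma::cube& x) {
  const int h = x.n_rows, w2 = x.n_cols, C = x.n_slices;
  cube y(2 * h, 2 * w2, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w2; ++j)
      for (int i = 0; i < h; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube upsample2_bwd(const arma::cube& dy) {
  const int h = dy.n_rows / 2, w2 = dy.n_cols / 2, C = dy.n_slices;
  cube dx(h, w2, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w2; ++j)
      for (int i = 0; i < h; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}
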