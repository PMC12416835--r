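// Minimal dense conv-net primitives for the desk-scale reference backbone.
// Tensors are R arrays dim (H, W, C) == arma::cube (rows, cols, slices).
// Weight matrix layout for a k x k conv: (Cout) x (Cin*k*k), with the
// input index running c (slice) slowest, then kernel col, then kernel row.
// im2col is laid out (H*W) x (Cin*k*k) so each kernel tap is one
// contiguous column, filled by block submatrix copies.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col(const cube& x, const int k) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices, pad = k / 2;
  mat col((size_t)h * w, cin * k * k, fill::zeros);
  for (int c = 0; c < cin; ++c) {
    for (int kc = 0; kc < k; ++kc) {
      const int dj = kc - pad;
      const int j0 = std::max(0, -dj), j1 = std::min(w, w - dj) - 1;
      for (int kr = 0; kr < k; ++kr) {
        const int di = kr - pad;
        const int i0 = std::max(0, -di), i1 = std::min(h, h - di) - 1;
        if (j0 > j1 || i0 > i1) continue;
        const int colidx = (c * k + kc) * k + kr;
        // view the column as an h x w image and block-copy the shifted
        // source window
        mat view(col.colptr(colidx), h, w, false, true);
        view.submat(i0, j0, i1, j1) =
          x.slice(c).submat(i0 + di, j0 + dj, i1 + di, j1 + dj);
      }
    }
  }
  return col;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, const int k) {
  const int h = x.n_rows, w = x.n_cols, cout = W.n_rows;
  mat out = im2col(x, k) * W.t();        // (h*w) x cout
  out.each_row() += b.t();
  cube y(h, w, cout);
  std::memcpy(y.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& W,
                      const arma::cube& gy, const int k) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int cout = W.n_rows, pad = k / 2;
  mat gout((size_t)h * w, cout);
  std::memcpy(gout.memptr(), gy.memptr(), sizeof(double) * gout.n_elem);
  mat col = im2col(x, k);
  mat gW = gout.t() * col;               // cout x (cin*k*k)
  vec gb = sum(gout, 0).t();
  mat gcol = gout * W;                   // (h*w) x (cin*k*k)
  cube gx(h, w, cin, fill::zeros);
  for (int c = 0; c < cin; ++c) {
    for (int kc = 0; kc < k; ++kc) {
      const int dj = kc - pad;
      const int j0 = std::max(0, -dj), j1 = std::min(w, w - dj) - 1;
      for (int kr = 0; kr < k; ++kr) {
        const int di = kr - pad;
        const int i0 = std::max(0, -di), i1 = std::min(h, h - di) - 1;
        if (j0 > j1 || i0 > i1) continue;
        const int colidx = (c * k + kc) * k + kr;
        mat view(gcol.colptr(colidx), h, w, false, true);
        gx.slice(c).submat(i0 + di, j0 + dj, i1 + di, j1 + dj) +=
          view.submat(i0, j0, i1, j1);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// 2x2 average pooling (even input sizes only — enforced by the architecture).
// [[Rcpp::export(name = ".avgpool2_fwd")]]
arma::cube avgpool2_fwd(const arma::cube& x) {
  const int h = x.n_rows / 2, w = x.n_cols / 2, c = x.n_slices;
  cube y(h, w, c);
  for (int s = 0; s < c; ++s)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i)
        y(i, j, s) = 0.25 * (x(2*i, 2*j, s) + x(2*i+1, 2*j, s) +
                             x(2*i, 2*j+1, s) + x(2*i+1, 2*j+1, s));
  return y;
}

// [[Rcpp::export(name = ".avgpool2_bwd")]]
arma::cube avgpool2_bwd(const arma::cube& gy) {
  const int h = gy.n_rows, w = gy.n_cols, c = gy.n_slices;
  cube gx(2 * h, 2 * w, c);
  for (int s = 0; s < c; ++s)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        const double g = 0.25 * gy(i, j, s);
        gx(2*i, 2*j, s) = g; gx(2*i+1, 2*j, s) = g;
        gx(2*i, 2*j+1, s) = g; gx(2*i+1, 2*j+1, s) = g;
      }
  return gx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export(name = ".upsample2_fwd")]]
arma::cube upsample2_fwd(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  cube y(2 * h, 2 * w, c);
  for (int s = 0; s < c; ++s)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        const double v = x(i, j, s);
        y(2*i, 2*j, s) = v; y(2*i+1, 2*j, s) = v;
        y(2*i, 2*j+1, s) = v; y(2*i+1, 2*j+1, s) = v;
      }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
arma::cube upsample2_bwd(const arma::cube& gy) {
  const int h = gy.n_rows / 2, w = gy.n_cols / 2, c = gy.n_slices;
  cube gx(h, w, c);
  for (int s = 0; s < c; ++s)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i)
        gx(i, j, s) = gy(2*i, 2*j, s) + gy(2*i+1, 2*j, s) +
                      gy(2*i, 2*j+1, s) + gy(2*i+1, 2*j+1, s);
  return gx;
}
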