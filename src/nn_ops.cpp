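// Minimal dense conv-net kernels: 3x3 same-padding convolution via im2col +
// GEMM, and 2x2 max pooling. Feature maps are H x W x C cubes (column-major,
// matching R arrays); weights are (9*Cin) x Cout matrices with column order
// cin-major, then kernel row, then kernel col.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void im2col3(const cube& x, mat& cols) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cols.zeros(H * W, 9 * C);
  for (uword c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int ky = -1; ky <= 1; ++ky) {
      for (int kx = -1; kx <= 1; ++kx) {
        const uword col = c * 9 + (ky + 1) * 3 + (kx + 1);
        mat s(H, W, fill::zeros);
        const uword r0 = ky < 0 ? 1 : 0, r1 = ky > 0 ? H - 2 : H - 1;
        const uword c0 = kx < 0 ? 1 : 0, c1 = kx > 0 ? W - 2 : W - 1;
        // s(i, j) = xc(i + ky, j + kx), zero outside the image
        s.submat(r0, c0, r1, c1) = xc.submat(r0 + ky, c0 + kx, r1 + ky, c1 + kx);
        cols.col(col) = vectorise(s);
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::List conv3x3_forward(const arma::cube& x, const arma::mat& w,
                           const arma::vec& b) {
  const uword H = x.n_rows, W = x.n_cols;
  const uword Cout = w.n_cols;
  mat cols;
  im2col3(x, cols);
  mat out = cols * w;
  out.each_row() += b.t();
  cube y(out.memptr(), H, W, Cout);
  return Rcpp::List::create(Rcpp::Named("out") = y, Rcpp::Named("cols") = cols);
}

// [[Rcpp::export]]
Rcpp::List conv3x3_backward(const arma::cube& dout, const arma::mat& cols,
                            const arma::mat& w, const int cin) {
  const uword H = dout.n_rows, W = dout.n_cols, Cout = dout.n_slices;
  mat dout_mat(const_cast<double*>(dout.memptr()), H * W, Cout, false, true);
  mat dw = cols.t() * dout_mat;
  vec db = sum(dout_mat, 0).t();
  mat dcols = dout_mat * w.t();
  cube dx(H, W, (uword)cin, fill::zeros);
  for (uword c = 0; c < (uword)cin; ++c) {
    for (int ky = -1; ky <= 1; ++ky) {
      for (int kx = -1; kx <= 1; ++kx) {
        const uword col = c * 9 + (ky + 1) * 3 + (kx + 1);
        mat s(dcols.colptr(col), H, W, false, true);
        const uword r0 = ky < 0 ? 1 : 0, r1 = ky > 0 ? H - 2 : H - 1;
        const uword c0 = kx < 0 ? 1 : 0, c1 = kx > 0 ? W - 2 : W - 1;
        // scatter-add: dx(i + ky, j + kx) += dcols(i, j)
        dx.slice(c).submat(r0 + ky, c0 + kx, r1 + ky, c1 + kx) +=
            s.submat(r0, c0, r1, c1);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List maxpool2_forward(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  ucube idx(Ho, Wo, C); // 0..3: which corner of the 2x2 block won
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < Wo; ++j) {
      for (uword i = 0; i < Ho; ++i) {
        const double v00 = x(2 * i, 2 * j, c), v10 = x(2 * i + 1, 2 * j, c);
        const double v01 = x(2 * i, 2 * j + 1, c),
                     v11 = x(2 * i + 1, 2 * j + 1, c);
        double best = v00;
        uword k = 0;
        if (v10 > best) { best = v10; k = 1; }
        if (v01 > best) { best = v01; k = 2; }
        if (v11 > best) { best = v11; k = 3; }
        y(i, j, c) = best;
        idx(i, j, c) = k;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_backward(const arma::cube& dout, const arma::ucube& idx) {
  const uword Ho = dout.n_rows, Wo = dout.n_cols, C = dout.n_slices;
  cube dx(Ho * 2, Wo * 2, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < Wo; ++j) {
      for (uword i = 0; i < Ho; ++i) {
        const uword k = idx(i, j, c);
        dx(2 * i + (k == 1 || k == 3), 2 * j + (k >= 2), c) = dout(i, j, c);
      }
    }
  }
  return dx;
}
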