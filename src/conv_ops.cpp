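// GEMM-backed layer primitives for the U-Net segmenter.
//
// Feature maps are arma::cube (H x W x C, column-major, matching R arrays).
// 3x3 convolutions use im2col + matrix multiply with zero ("same") padding.
// The patch matrix is laid out (H*W) x (9*C) so that the inner copy loops
// run down contiguous memory; weights are [C_out x (9*C_in)] with patch
// column index c*9 + (dj+1)*3 + (di+1), di/dj in {-1,0,1} over rows/cols.
// 2x2 up-convolutions (transposed conv, stride 2) use weights
// [C_out x (4*C_in)] with offset index o = dj*2 + di, di/dj in {0,1}.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// patch matrix (H*W) x (9*C): column r = shifted copy of channel c
static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out((uword)H * W, 9 * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        double* dst = out.colptr(c * 9 + (dj + 1) * 3 + (di + 1));
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          const double* src = xc.colptr(j + dj) + di;
          double* d = dst + (uword)j * H;
          for (int i = i0; i < i1; ++i) d[i] = src[i];
        }
      }
    }
  }
  return out;
}

// scatter-add the (H*W) x (9*C) gradient patches back onto the input grid
static void col2im3_add(const mat& colT, cube& gx) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; ++c) {
    mat& gc = gx.slice(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const double* src = colT.colptr(c * 9 + (dj + 1) * 3 + (di + 1));
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          double* dst = gc.colptr(j + dj) + di;
          const double* s = src + (uword)j * H;
          for (int i = i0; i < i1; ++i) dst[i] += s[i];
        }
      }
    }
  }
}

// cube (H x W x C) <-> flat matrix (H*W x C): slices are already contiguous
static mat flat_view(const cube& x) {
  return mat(const_cast<double*>(x.memptr()), x.n_rows * x.n_cols, x.n_slices,
             false, true);
}

static cube cube_from_flat(const mat& m, uword H, uword W) {
  cube out(H, W, m.n_cols);
  std::memcpy(out.memptr(), m.memptr(), sizeof(double) * m.n_elem);
  return out;
}

// [[Rcpp::export]]
arma::cube conv3_fwd(const arma::cube& x, const arma::mat& W,
                     const arma::vec& b) {
  mat colT = im2col3(x);
  mat y = colT * W.t(); // (HW x Cout)
  y.each_row() += b.t();
  return cube_from_flat(y, x.n_rows, x.n_cols);
}

// [[Rcpp::export]]
Rcpp::List conv3_bwd(const arma::cube& x, const arma::mat& W,
                     const arma::cube& gy) {
  mat colT = im2col3(x);
  mat gyT = flat_view(gy); // (HW x Cout)
  mat gW = gyT.t() * colT; // (Cout x 9C)
  vec gb = sum(gyT, 0).t();
  mat gcolT = gyT * W; // (HW x 9C)
  cube gx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  col2im3_add(gcolT, gx);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
arma::cube conv1_fwd(const arma::cube& x, const arma::mat& W,
                     const arma::vec& b) {
  mat y = flat_view(x) * W.t();
  y.each_row() += b.t();
  return cube_from_flat(y, x.n_rows, x.n_cols);
}

// [[Rcpp::export]]
Rcpp::List conv1_bwd(const arma::cube& x, const arma::mat& W,
                     const arma::cube& gy) {
  mat xT = flat_view(x);
  mat gyT = flat_view(gy);
  mat gW = gyT.t() * xT;
  vec gb = sum(gyT, 0).t();
  mat gxT = gyT * W;
  return Rcpp::List::create(Rcpp::Named("gx") = cube_from_flat(gxT, x.n_rows, x.n_cols),
                            Rcpp::Named("gW") = gW, Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
Rcpp::List maxpool2_fwd(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  ucube idx(Ho, Wo, C); // linear index into the input slice
  for (uword c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (uword j = 0; j < Wo; ++j) {
      const double* c0 = xc.colptr(2 * j);
      const double* c1 = xc.colptr(2 * j + 1);
      for (uword i = 0; i < Ho; ++i) {
        const uword bi = 2 * i;
        double v = c0[bi];
        uword best = 2 * j * H + bi;
        if (c0[bi + 1] > v) { v = c0[bi + 1]; best = 2 * j * H + bi + 1; }
        if (c1[bi] > v) { v = c1[bi]; best = (2 * j + 1) * H + bi; }
        if (c1[bi + 1] > v) { v = c1[bi + 1]; best = (2 * j + 1) * H + bi + 1; }
        y(i, j, c) = v;
        idx(i, j, c) = best;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::cube& gy, const arma::ucube& idx,
                        int H, int W) {
  const uword C = gy.n_slices, Ho = gy.n_rows, Wo = gy.n_cols;
  cube gx(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    double* gc = gx.slice_memptr(c);
    for (uword j = 0; j < Wo; ++j)
      for (uword i = 0; i < Ho; ++i) gc[idx(i, j, c)] += gy(i, j, c);
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube upconv2_fwd(const arma::cube& x, const arma::mat& W,
                       const arma::vec& b) {
  const uword H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices, Cout = W.n_rows;
  mat xT = flat_view(x); // (HW x Cin)
  cube out(2 * H, 2 * Wd, Cout);
  for (uword o = 0; o < 4; ++o) {
    const uword di = o % 2, dj = o / 2;
    mat Wo(Cout, Cin);
    for (uword ci = 0; ci < Cin; ++ci) Wo.col(ci) = W.col(ci * 4 + o);
    mat yo = xT * Wo.t(); // (HW x Cout); each output pixel gets one term
    for (uword c = 0; c < Cout; ++c) {
      const double* src = yo.colptr(c);
      const double bc = b(c);
      for (uword j = 0; j < Wd; ++j) {
        double* dst = out.slice_memptr(c) + (2 * j + dj) * 2 * H + di;
        const double* s = src + j * H;
        for (uword i = 0; i < H; ++i) dst[2 * i] = s[i] + bc;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List upconv2_bwd(const arma::cube& x, const arma::mat& W,
                       const arma::cube& gy) {
  const uword H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices,
              Cout = gy.n_slices;
  mat xT = flat_view(x);
  mat gW(Cout, 4 * Cin, fill::zeros);
  vec gb(Cout, fill::zeros);
  mat gxT(H * Wd, Cin, fill::zeros);
  mat gyo(H * Wd, Cout);
  for (uword o = 0; o < 4; ++o) {
    const uword di = o % 2, dj = o / 2;
    for (uword c = 0; c < Cout; ++c) {
      double* dst = gyo.colptr(c);
      for (uword j = 0; j < Wd; ++j) {
        const double* src = gy.slice_memptr(c) + (2 * j + dj) * 2 * H + di;
        double* d = dst + j * H;
        for (uword i = 0; i < H; ++i) d[i] = src[2 * i];
      }
    }
    mat Wo(Cout, Cin);
    for (uword ci = 0; ci < Cin; ++ci) Wo.col(ci) = W.col(ci * 4 + o);
    mat gWo = gyo.t() * xT; // (Cout x Cin)
    for (uword ci = 0; ci < Cin; ++ci) gW.col(ci * 4 + o) = gWo.col(ci);
    gb += sum(gyo, 0).t();
    gxT += gyo * Wo;
  }
  return Rcpp::List::create(Rcpp::Named("gx") = cube_from_flat(gxT, H, Wd),
                            Rcpp::Named("gW") = gW, Rcpp::Named("gb") = gb);
}
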