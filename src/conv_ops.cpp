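// Minimal convolution primitives for small encoder-decoder networks.
// Layout convention: images are H x W x C cubes (R arrays, column-major);
// conv weights are k x k x Cin x Cout; up-conv weights are 2 x 2 x Cin x Cout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::cube pad_cube(const arma::cube& x, int p) {
  if (p == 0) return x;
  arma::cube xp(x.n_rows + 2 * p, x.n_cols + 2 * p, x.n_slices, arma::fill::zeros);
  xp.subcube(p, p, 0, p + x.n_rows - 1, p + x.n_cols - 1, x.n_slices - 1) = x;
  return xp;
}

// im2col with kr fastest, then kc, then ci (matches R's column-major
// flattening of a k x k x Cin weight block); output columns ordered with
// output-row index fastest.
static arma::mat im2col(const arma::cube& xp, int k, int s, int Hout, int Wout) {
  const int Cin = xp.n_slices;
  arma::mat cols(k * k * Cin, (size_t)Hout * Wout);
  for (int ow = 0; ow < Wout; ++ow) {
    for (int oh = 0; oh < Hout; ++oh) {
      const size_t q = (size_t)ow * Hout + oh;
      double* dst = cols.colptr(q);
      for (int ci = 0; ci < Cin; ++ci) {
        for (int kc = 0; kc < k; ++kc) {
          const double* src = xp.slice_colptr(ci, ow * s + kc) + oh * s;
          for (int kr = 0; kr < k; ++kr) dst[ci * k * k + kc * k + kr] = src[kr];
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::vec& w_flat,
                      const arma::vec& b, int k, int Cout, int stride, int pad) {
  const int Cin = x.n_slices;
  const int Hout = (x.n_rows + 2 * pad - k) / stride + 1;
  const int Wout = (x.n_cols + 2 * pad - k) / stride + 1;
  arma::cube xp = pad_cube(x, pad);
  arma::mat cols = im2col(xp, k, stride, Hout, Wout);
  arma::mat W(const_cast<double*>(w_flat.memptr()), k * k * Cin, Cout, false, true);
  arma::mat Y = cols.t() * W;             // [Hout*Wout, Cout]
  Y.each_row() += b.t();
  return arma::cube(Y.memptr(), Hout, Wout, Cout);
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(const arma::cube& x, const arma::vec& w_flat,
                const arma::cube& gout, int k, int stride, int pad) {
  const int Cin = x.n_slices, Cout = gout.n_slices;
  const int Hout = gout.n_rows, Wout = gout.n_cols;
  arma::cube xp = pad_cube(x, pad);
  arma::mat cols = im2col(xp, k, stride, Hout, Wout);
  arma::mat G(const_cast<double*>(gout.memptr()), (size_t)Hout * Wout, Cout, false, true);
  arma::mat gw = cols * G;                          // [k*k*Cin, Cout]
  arma::vec gb = arma::sum(G, 0).t();
  arma::mat W(const_cast<double*>(w_flat.memptr()), k * k * Cin, Cout, false, true);
  arma::mat gcols = W * G.t();                      // [k*k*Cin, Hout*Wout]
  arma::cube gxp(xp.n_rows, xp.n_cols, Cin, arma::fill::zeros);
  for (int ow = 0; ow < Wout; ++ow) {
    for (int oh = 0; oh < Hout; ++oh) {
      const size_t q = (size_t)ow * Hout + oh;
      const double* src = gcols.colptr(q);
      for (int ci = 0; ci < Cin; ++ci) {
        for (int kc = 0; kc < k; ++kc) {
          double* dst = gxp.slice_colptr(ci, ow * stride + kc) + oh * stride;
          for (int kr = 0; kr < k; ++kr) dst[kr] += src[ci * k * k + kc * k + kr];
        }
      }
    }
  }
  arma::cube gx = (pad == 0) ? gxp
    : arma::cube(gxp.subcube(pad, pad, 0, pad + x.n_rows - 1, pad + x.n_cols - 1, Cin - 1));
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Stride-2 up-convolution with a 2x2 kernel: each input pixel expands to a
// non-overlapping 2x2 output block (the original U-Net "up-conv").
// [[Rcpp::export(name = ".tconv2_fwd")]]
arma::cube tconv2_fwd(const arma::cube& x, const arma::vec& w_flat,
                      const arma::vec& b, int Cout) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  arma::mat X(const_cast<double*>(x.memptr()), (size_t)H * W, Cin, false, true);
  arma::cube y(2 * H, 2 * W, Cout);
  for (int co = 0; co < Cout; ++co) y.slice(co).fill(b(co));
  for (int dj = 0; dj < 2; ++dj) {
    for (int di = 0; di < 2; ++di) {
      arma::mat Wo(Cin, Cout);
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          Wo(ci, co) = w_flat(((size_t)co * Cin + ci) * 4 + dj * 2 + di);
      arma::mat Yo = X * Wo;                        // [H*W, Cout]
      for (int co = 0; co < Cout; ++co) {
        const double* src = Yo.colptr(co);
        for (int j = 0; j < W; ++j) {
          double* dst = y.slice_colptr(co, 2 * j + dj) + di;
          const double* s2 = src + (size_t)j * H;
          for (int i = 0; i < H; ++i) dst[2 * i] += s2[i];
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".tconv2_bwd")]]
List tconv2_bwd(const arma::cube& x, const arma::vec& w_flat,
                const arma::cube& gout) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gout.n_slices;
  arma::mat X(const_cast<double*>(x.memptr()), (size_t)H * W, Cin, false, true);
  arma::cube gx(H, W, Cin, arma::fill::zeros);
  arma::mat gxm((double*)gx.memptr(), (size_t)H * W, Cin, false, true);
  arma::vec gw(w_flat.n_elem, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co) gb(co) = arma::accu(gout.slice(co));
  for (int dj = 0; dj < 2; ++dj) {
    for (int di = 0; di < 2; ++di) {
      arma::mat Go((size_t)H * W, Cout);
      for (int co = 0; co < Cout; ++co) {
        double* dst = Go.colptr(co);
        for (int j = 0; j < W; ++j) {
          const double* src = gout.slice_colptr(co, 2 * j + dj) + di;
          double* d2 = dst + (size_t)j * H;
          for (int i = 0; i < H; ++i) d2[i] = src[2 * i];
        }
      }
      arma::mat gWo = X.t() * Go;                   // [Cin, Cout]
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          gw(((size_t)co * Cin + ci) * 4 + dj * 2 + di) = gWo(ci, co);
      arma::mat Wo(Cin, Cout);
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          Wo(ci, co) = w_flat(((size_t)co * Cin + ci) * 4 + dj * 2 + di);
      gxm += Go * Wo.t();
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
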