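// Native layer kernels for the single-stream FCN: valid/padded convolution,
// ceiling-mode 2x2/2 max pooling, and strided transposed convolution, each
// with forward and backward passes. Rasters are R arrays (H, W, C), i.e.
// arma::cube memory layout; convolutions are evaluated as one GEMM per kernel
// offset so the heavy lifting runs on BLAS without an im2col blow-up.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::cube as_cube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  return arma::cube(const_cast<double*>(x.begin()), d[0], d[1], d[2], false, true);
}

// single-precision copies: convolution GEMMs run in float32 for speed
static arma::fcube as_fcube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array");
  arma::fcube out(d[0], d[1], d[2]);
  std::copy(x.begin(), x.end(), out.memptr());
  return out;
}

static NumericVector wrap_fcube(const arma::fcube& c) {
  NumericVector out(c.n_elem);
  std::copy(c.begin(), c.end(), out.begin());
  out.attr("dim") = IntegerVector::create(c.n_rows, c.n_cols, c.n_slices);
  return out;
}

static arma::fcube weight_fcube(const NumericVector& w, int k, int cin, int cout) {
  arma::fcube out(k * k, cin, cout);
  std::copy(w.begin(), w.end(), out.memptr());
  return out;
}

static NumericVector wrap_cube(const arma::cube& c) {
  NumericVector out(c.begin(), c.end());
  out.attr("dim") = IntegerVector::create(c.n_rows, c.n_cols, c.n_slices);
  return out;
}

// weights (k, k, Cin, Cout) viewed as cube (k*k, Cin, Cout)
static arma::cube weight_cube(const NumericVector& w, int k, int cin, int cout) {
  return arma::cube(const_cast<double*>(w.begin()), k * k, cin, cout, false, true);
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x_, NumericVector w_, NumericVector b_, int pad) {
  arma::fcube x = as_fcube(x_);
  IntegerVector wd = w_.attr("dim");
  if (wd.size() != 4) stop("conv weights must be (k, k, Cin, Cout)");
  const int k = wd[0], cin = wd[2], cout = wd[3];
  if (wd[1] != k) stop("conv kernels must be square");
  if ((int)x.n_slices != cin) stop("input channel mismatch");
  arma::fcube wc = weight_fcube(w_, k, cin, cout);
  arma::fvec b(cout);
  std::copy(b_.begin(), b_.end(), b.memptr());

  const int H = x.n_rows, W = x.n_cols;
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int Ho = Hp - k + 1, Wo = Wp - k + 1;
  if (Ho < 1 || Wo < 1) stop("convolution collapses the feature map");

  arma::fcube xp(Hp, Wp, cin, arma::fill::zeros);
  xp.subcube(pad, pad, 0, pad + H - 1, pad + W - 1, cin - 1) = x;

  arma::fmat Y(Ho * (size_t)Wo, cout, arma::fill::zeros);
  arma::fmat Xo(Ho * (size_t)Wo, cin);
  arma::fmat Wk(cin, cout);
  for (int kj = 0; kj < k; ++kj) {
    for (int ki = 0; ki < k; ++ki) {
      const int q = ki + k * kj;
      for (int ci = 0; ci < cin; ++ci)
        Xo.col(ci) = arma::vectorise(xp.slice(ci).submat(ki, kj, ki + Ho - 1, kj + Wo - 1));
      for (int co = 0; co < cout; ++co)
        Wk.col(co) = wc.slice(co).row(q).t();
      Y += Xo * Wk;
    }
  }
  Y.each_row() += b.t();
  arma::fcube yc(Y.memptr(), Ho, Wo, cout);
  return wrap_fcube(yc);
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x_, NumericVector w_, NumericVector dy_, int pad) {
  arma::fcube x = as_fcube(x_);
  arma::fcube dyc = as_fcube(dy_);
  IntegerVector wd = w_.attr("dim");
  const int k = wd[0], cin = wd[2], cout = wd[3];
  arma::fcube wc = weight_fcube(w_, k, cin, cout);

  const int H = x.n_rows, W = x.n_cols;
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int Ho = dyc.n_rows, Wo = dyc.n_cols;

  arma::fcube xp(Hp, Wp, cin, arma::fill::zeros);
  xp.subcube(pad, pad, 0, pad + H - 1, pad + W - 1, cin - 1) = x;

  arma::fmat dY(dyc.memptr(), Ho * (size_t)Wo, cout, false, true);
  arma::fcube dxp(Hp, Wp, cin, arma::fill::zeros);
  NumericVector dw_(k * k * cin * cout);
  dw_.attr("dim") = IntegerVector::create(k, k, cin, cout);
  arma::cube dwc(dw_.begin(), k * k, cin, cout, false, true);

  arma::fmat Xo(Ho * (size_t)Wo, cin);
  arma::fmat Wk(cin, cout);
  for (int kj = 0; kj < k; ++kj) {
    for (int ki = 0; ki < k; ++ki) {
      const int q = ki + k * kj;
      for (int ci = 0; ci < cin; ++ci)
        Xo.col(ci) = arma::vectorise(xp.slice(ci).submat(ki, kj, ki + Ho - 1, kj + Wo - 1));
      for (int co = 0; co < cout; ++co)
        Wk.col(co) = wc.slice(co).row(q).t();
      arma::fmat dWk = Xo.t() * dY;                 // (Cin, Cout)
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          dwc(q, ci, co) = dWk(ci, co);
      arma::fmat dXo = dY * Wk.t();                 // (Ho*Wo, Cin)
      for (int ci = 0; ci < cin; ++ci)
        dxp.slice(ci).submat(ki, kj, ki + Ho - 1, kj + Wo - 1) +=
          arma::reshape(dXo.col(ci), Ho, Wo);
    }
  }
  arma::fcube dx = dxp.subcube(pad, pad, 0, pad + H - 1, pad + W - 1, cin - 1);
  NumericVector db_(cout);
  for (int co = 0; co < cout; ++co) db_[co] = arma::accu(dY.col(co));
  return List::create(_["dx"] = wrap_fcube(dx), _["dw"] = dw_, _["db"] = db_);
}

// 2x2 stride-2 max pooling, ceiling-mode output size ceil(H/2) x ceil(W/2);
// edge windows are clipped. Ties take the first element in column-major scan
// order, so pooling is deterministic.
// [[Rcpp::export]]
List cpp_pool_fwd(NumericVector x_) {
  arma::cube x = as_cube(x_);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  arma::cube y(Ho, Wo, C);
  IntegerVector idx_(Ho * Wo * C);          // 0-based index into the (H, W) plane
  idx_.attr("dim") = IntegerVector::create(Ho, Wo, C);
  int* idx = idx_.begin();
  for (int c = 0; c < C; ++c) {
    const arma::mat& s = x.slice(c);
    for (int ow = 0; ow < Wo; ++ow) {
      const int w0 = 2 * ow, w1 = std::min(2 * ow + 1, W - 1);
      for (int oh = 0; oh < Ho; ++oh) {
        const int h0 = 2 * oh, h1 = std::min(2 * oh + 1, H - 1);
        double best = s(h0, w0);
        int bh = h0, bw = w0;
        for (int ww = w0; ww <= w1; ++ww)
          for (int hh = h0; hh <= h1; ++hh)
            if (s(hh, ww) > best) { best = s(hh, ww); bh = hh; bw = ww; }
        y(oh, ow, c) = best;
        idx[oh + Ho * (ow + (size_t)Wo * c)] = bh + H * bw;
      }
    }
  }
  return List::create(_["y"] = wrap_cube(y), _["idx"] = idx_);
}

// [[Rcpp::export]]
NumericVector cpp_pool_bwd(IntegerVector idx_, int H, int W, NumericVector dy_) {
  arma::cube dy = as_cube(dy_);
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  const int* idx = idx_.begin();
  for (int c = 0; c < C; ++c) {
    double* dslice = dx.slice(c).memptr();
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh)
        dslice[idx[oh + Ho * (ow + (size_t)Wo * c)]] += dy(oh, ow, c);
  }
  return wrap_cube(dx);
}

// Transposed convolution: output side (S - 1) * stride + k.
// [[Rcpp::export]]
NumericVector cpp_deconv_fwd(NumericVector x_, NumericVector w_, NumericVector b_, int stride) {
  arma::cube x = as_cube(x_);
  IntegerVector wd = w_.attr("dim");
  const int k = wd[0], cin = wd[2], cout = wd[3];
  if ((int)x.n_slices != cin) stop("input channel mismatch");
  arma::cube wc = weight_cube(w_, k, cin, cout);
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H - 1) * stride + k, Wo = (W - 1) * stride + k;
  arma::cube y(Ho, Wo, cout, arma::fill::zeros);
  for (int co = 0; co < cout; ++co) {
    arma::mat& ys = y.slice(co);
    for (int ci = 0; ci < cin; ++ci) {
      arma::mat ker(wc.slice(co).colptr(ci), k, k, false, true);
      for (int iw = 0; iw < W; ++iw)
        for (int ih = 0; ih < H; ++ih) {
          const double v = x(ih, iw, ci);
          if (v != 0.0)
            ys.submat(ih * stride, iw * stride, ih * stride + k - 1, iw * stride + k - 1)
              += v * ker;
        }
    }
    ys += b_[co];
  }
  return wrap_cube(y);
}

// [[Rcpp::export]]
List cpp_deconv_bwd(NumericVector x_, NumericVector w_, NumericVector dy_, int stride) {
  arma::cube x = as_cube(x_);
  arma::cube dy = as_cube(dy_);
  IntegerVector wd = w_.attr("dim");
  const int k = wd[0], cin = wd[2], cout = wd[3];
  arma::cube wc = weight_cube(w_, k, cin, cout);
  const int H = x.n_rows, W = x.n_cols;
  arma::cube dx(H, W, cin, arma::fill::zeros);
  NumericVector dw_(k * k * cin * cout);
  dw_.attr("dim") = IntegerVector::create(k, k, cin, cout);
  arma::cube dwc(dw_.begin(), k * k, cin, cout, false, true);
  NumericVector db_(cout);
  for (int co = 0; co < cout; ++co) {
    const arma::mat& dys = dy.slice(co);
    db_[co] = arma::accu(dys);
    for (int ci = 0; ci < cin; ++ci) {
      arma::mat ker(wc.slice(co).colptr(ci), k, k, false, true);
      arma::mat dker(k, k, arma::fill::zeros);
      for (int iw = 0; iw < W; ++iw)
        for (int ih = 0; ih < H; ++ih) {
          arma::mat win = dys.submat(ih * stride, iw * stride,
                                     ih * stride + k - 1, iw * stride + k - 1);
          dx(ih, iw, ci) += arma::accu(win % ker);
          dker += x(ih, iw, ci) * win;
        }
      dwc.slice(co).col(ci) = arma::vectorise(dker);
    }
  }
  return List::create(_["dx"] = wrap_cube(dx), _["dw"] = dw_, _["db"] = db_);
}
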