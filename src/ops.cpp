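// Low-level dense-array ops for 3D conv nets, warping and filtering.
// Tensors are R numeric arrays, channel-first: dim = (C, D, H, W).
// Plain 3D volumes are (D, H, W). Displacement fields are (3, D, H, W),
// channel d holding the displacement along axis d in voxel units.

#include <RcppArmadillo.h>
#include <limits>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Convolutions run in single precision through chunked im2col (one
// output w-slice at a time) and sgemm, with reused scratch buffers; this
// keeps the working set cache-resident. Parameters and activations live in
// R as doubles; conversion happens at the boundary.

static std::vector<float> &scratch(int which, size_t n) {
  static std::vector<float> bufs[6];
  if (bufs[which].size() < n) bufs[which].resize(n);
  return bufs[which];
}

static void to_float(const double *src, float *dst, size_t n) {
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
}

// valid output range [lo, hi) along one axis for a kernel offset
static inline void orange(int n_in, int n_out, int s, int p, int koff,
                          int &lo, int &hi) {
  // input index = o*s - p + koff must lie in [0, n_in)
  lo = 0;
  while (lo < n_out && lo * s - p + koff < 0) ++lo;
  hi = n_out;
  while (hi > lo && (hi - 1) * s - p + koff >= n_in) --hi;
}

// fill the im2col chunk for output slice ow: K x (Do*Ho) floats.
// Offsets are the outer loops so the interior runs branch-free.
static void im2col_slice(const float *x, int C, int D, int H, int W,
                         int k, int s, int p, int Do, int Ho, int ow,
                         float *cols) {
  const int K = C * k * k * k;
  std::fill(cols, cols + (size_t)K * Do * Ho, 0.0f);
  for (int kw = 0; kw < k; ++kw) {
    int w = ow * s - p + kw;
    if (w < 0 || w >= W) continue;
    for (int kh = 0; kh < k; ++kh) {
      int hlo, hhi; orange(H, Ho, s, p, kh, hlo, hhi);
      for (int kd = 0; kd < k; ++kd) {
        int dlo, dhi; orange(D, Do, s, p, kd, dlo, dhi);
        size_t roff = (size_t)C * (kd + k * (kh + k * kw));
        for (int oh = hlo; oh < hhi; ++oh) {
          int h = oh * s - p + kh;
          const float *srow = x + (size_t)C * ((size_t)D * (h + (size_t)H * w));
          float *drow = cols + roff + (size_t)K * ((size_t)Do * oh);
          for (int od = dlo; od < dhi; ++od) {
            const float *src = srow + (size_t)C * (od * s - p + kd);
            float *dc = drow + (size_t)K * od;
            for (int c = 0; c < C; ++c) dc[c] = src[c];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int C = xd[0], D = xd[1], H = xd[2], W = xd[3];
  int Cout = wd[0], Cin = wd[1], k = wd[2];
  if (Cin != C) stop("conv3d: input has %d channels, weight expects %d", C, Cin);
  int Do = out_size(D, k, stride, pad), Ho = out_size(H, k, stride, pad),
      Wo = out_size(W, k, stride, pad);
  const int K = C * k * k * k;
  float *xf = scratch(0, x.size()).data();
  float *wf = scratch(1, w.size()).data();
  to_float(x.begin(), xf, x.size());
  to_float(w.begin(), wf, w.size());
  float *cols = scratch(2, (size_t)K * Do * Ho).data();
  float *yf = scratch(3, (size_t)Cout * Do * Ho).data();
  arma::fmat Wm(wf, Cout, K, false, true);
  NumericVector out((size_t)Cout * Do * Ho * Wo);
  double *op = out.begin();
  for (int ow = 0; ow < Wo; ++ow) {
    im2col_slice(xf, C, D, H, W, k, stride, pad, Do, Ho, ow, cols);
    arma::fmat Cm(cols, K, (size_t)Do * Ho, false, true);
    arma::fmat Ym(yf, Cout, (size_t)Do * Ho, false, true);
    Ym = Wm * Cm;
    double *dst = op + (size_t)Cout * Do * Ho * ow;
    for (size_t j = 0; j < (size_t)Do * Ho; ++j)
      for (int c = 0; c < Cout; ++c)
        dst[c + Cout * j] = yf[c + Cout * j] + b[c];
  }
  out.attr("dim") = IntegerVector::create(Cout, Do, Ho, Wo);
  return out;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad, bool want_gx = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int C = xd[0], D = xd[1], H = xd[2], W = xd[3];
  int Cout = wd[0], k = wd[2];
  int Do = gd[1], Ho = gd[2], Wo = gd[3];
  const int K = C * k * k * k;
  float *xf = scratch(0, x.size()).data();
  float *wf = scratch(1, w.size()).data();
  to_float(x.begin(), xf, x.size());
  to_float(w.begin(), wf, w.size());
  float *cols = scratch(2, (size_t)K * Do * Ho).data();
  float *gyf = scratch(3, gy.size()).data();
  to_float(gy.begin(), gyf, gy.size());
  float *gcols = scratch(4, (size_t)K * Do * Ho).data();
  float *gxf = scratch(5, x.size()).data();
  std::fill(gxf, gxf + x.size(), 0.0f);
  arma::fmat Wm(wf, Cout, K, false, true);
  arma::fmat gW(Cout, K, arma::fill::zeros);
  arma::fvec gb(Cout, arma::fill::zeros);
  for (int ow = 0; ow < Wo; ++ow) {
    im2col_slice(xf, C, D, H, W, k, stride, pad, Do, Ho, ow, cols);
    arma::fmat Cm(cols, K, (size_t)Do * Ho, false, true);
    arma::fmat Gy(gyf + (size_t)Cout * Do * Ho * ow, Cout,
                  (size_t)Do * Ho, false, true);
    gW += Gy * Cm.t();
    gb += arma::sum(Gy, 1);
    if (!want_gx) continue;
    arma::fmat Gc(gcols, K, (size_t)Do * Ho, false, true);
    Gc = Wm.t() * Gy;
    // col2im: scatter-add the chunk back into gx, offsets outermost
    for (int kw = 0; kw < k; ++kw) {
      int ww = ow * stride - pad + kw;
      if (ww < 0 || ww >= W) continue;
      for (int kh = 0; kh < k; ++kh) {
        int hlo, hhi; orange(H, Ho, stride, pad, kh, hlo, hhi);
        for (int kd = 0; kd < k; ++kd) {
          int dlo, dhi; orange(D, Do, stride, pad, kd, dlo, dhi);
          size_t roff = (size_t)C * (kd + k * (kh + k * kw));
          for (int oh = hlo; oh < hhi; ++oh) {
            int h = oh * stride - pad + kh;
            float *drow = gxf + (size_t)C * ((size_t)D * (h + (size_t)H * ww));
            const float *srow = gcols + roff + (size_t)K * ((size_t)Do * oh);
            for (int od = dlo; od < dhi; ++od) {
              const float *sc = srow + (size_t)K * od;
              float *dst = drow + (size_t)C * (od * stride - pad + kd);
              for (int c = 0; c < C; ++c) dst[c] += sc[c];
            }
          }
        }
      }
    }
  }
  NumericVector gx(want_gx ? x.size() : 0);
  if (want_gx) {
    gx.attr("dim") = xd;
    for (size_t i = 0; i < (size_t)x.size(); ++i) gx[i] = gxf[i];
  }
  NumericVector gwv(w.size());
  gwv.attr("dim") = wd;
  std::copy(gW.begin(), gW.end(), gwv.begin());
  NumericVector gbv(Cout);
  std::copy(gb.begin(), gb.end(), gbv.begin());
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
}

// Nearest-neighbour upsampling by 2 along the three spatial axes.
// [[Rcpp::export(name = ".upsample2_fwd")]]
NumericVector upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int C = xd[0], D = xd[1], H = xd[2], W = xd[3];
  int D2 = 2 * D, H2 = 2 * H, W2 = 2 * W;
  NumericVector y((size_t)C * D2 * H2 * W2);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int w = 0; w < W2; ++w)
    for (int h = 0; h < H2; ++h)
      for (int d = 0; d < D2; ++d) {
        const double *src = xp + (size_t)C * ((d / 2) + (size_t)D * ((h / 2) + (size_t)H * (w / 2)));
        double *dst = yp + (size_t)C * (d + (size_t)D2 * (h + (size_t)H2 * w));
        for (int c = 0; c < C; ++c) dst[c] = src[c];
      }
  y.attr("dim") = IntegerVector::create(C, D2, H2, W2);
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericVector upsample2_bwd(NumericVector gy) {
  IntegerVector gd = gy.attr("dim");
  int C = gd[0], D2 = gd[1], H2 = gd[2], W2 = gd[3];
  int D = D2 / 2, H = H2 / 2, W = W2 / 2;
  NumericVector gx((size_t)C * D * H * W);
  const double *gp = gy.begin();
  double *xp = gx.begin();
  for (int w = 0; w < W2; ++w)
    for (int h = 0; h < H2; ++h)
      for (int d = 0; d < D2; ++d) {
        const double *src = gp + (size_t)C * (d + (size_t)D2 * (h + (size_t)H2 * w));
        double *dst = xp + (size_t)C * ((d / 2) + (size_t)D * ((h / 2) + (size_t)H * (w / 2)));
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
  gx.attr("dim") = IntegerVector::create(C, D, H, W);
  return gx;
}

static inline double sample_border(const double *v, int D, int H, int W,
                                   int d, int h, int w) {
  d = d < 0 ? 0 : (d >= D ? D - 1 : d);
  h = h < 0 ? 0 : (h >= H ? H - 1 : h);
  w = w < 0 ? 0 : (w >= W ? W - 1 : w);
  return v[d + (size_t)D * (h + (size_t)H * w)];
}

static inline double sample_zero(const double *v, int D, int H, int W,
                                 int d, int h, int w) {
  if (d < 0 || d >= D || h < 0 || h >= H || w < 0 || w >= W) return 0.0;
  return v[d + (size_t)D * (h + (size_t)H * w)];
}

// Pull-style warp: out(p) = vol(p + u(p)). vol is (D,H,W), u is (3,D,H,W).
// interp: 0 = trilinear, 1 = nearest. padding: 0 = border, 1 = zeros.
// [[Rcpp::export(name = ".warp_fwd")]]
NumericVector warp_fwd(NumericVector vol, NumericVector u, int interp, int padding) {
  IntegerVector vd = vol.attr("dim");
  int D = vd[0], H = vd[1], W = vd[2];
  NumericVector out((size_t)D * H * W);
  const double *vp = vol.begin(), *up = u.begin();
  double *op = out.begin();
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        size_t q = d + (size_t)D * (h + (size_t)H * w);
        double xd = d + up[3 * q], xh = h + up[3 * q + 1], xw = w + up[3 * q + 2];
        if (!std::isfinite(xd) || !std::isfinite(xh) || !std::isfinite(xw)) {
          op[q] = std::numeric_limits<double>::quiet_NaN();
          continue;
        }
        if (interp == 1) {
          int id = (int)std::floor(xd + 0.5), ih = (int)std::floor(xh + 0.5),
              iw = (int)std::floor(xw + 0.5);
          op[q] = padding == 0 ? sample_border(vp, D, H, W, id, ih, iw)
                               : sample_zero(vp, D, H, W, id, ih, iw);
        } else {
          if (padding == 0) {
            xd = std::min(std::max(xd, 0.0), (double)(D - 1));
            xh = std::min(std::max(xh, 0.0), (double)(H - 1));
            xw = std::min(std::max(xw, 0.0), (double)(W - 1));
          }
          int fd = (int)std::floor(xd), fh = (int)std::floor(xh), fw = (int)std::floor(xw);
          double td = xd - fd, th = xh - fh, tw = xw - fw;
          double acc = 0.0;
          for (int cw = 0; cw < 2; ++cw)
            for (int ch = 0; ch < 2; ++ch)
              for (int cd = 0; cd < 2; ++cd) {
                double wt = (cd ? td : 1 - td) * (ch ? th : 1 - th) * (cw ? tw : 1 - tw);
                if (wt == 0.0) continue;
                double val = padding == 0
                  ? sample_border(vp, D, H, W, fd + cd, fh + ch, fw + cw)
                  : sample_zero(vp, D, H, W, fd + cd, fh + ch, fw + cw);
                acc += wt * val;
              }
          op[q] = acc;
        }
      }
  out.attr("dim") = vd;
  return out;
}

// Gradients of the trilinear warp w.r.t. both the volume and the field.
// [[Rcpp::export(name = ".warp_bwd")]]
List warp_bwd(NumericVector vol, NumericVector u, NumericVector gy, int padding) {
  IntegerVector vd = vol.attr("dim");
  int D = vd[0], H = vd[1], W = vd[2];
  NumericVector gvol((size_t)D * H * W), gu((size_t)3 * D * H * W);
  const double *vp = vol.begin(), *up = u.begin(), *gp = gy.begin();
  double *gvp = gvol.begin(), *gup = gu.begin();
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        size_t q = d + (size_t)D * (h + (size_t)H * w);
        double g = gp[q];
        if (g == 0.0) continue;
        double xd = d + up[3 * q], xh = h + up[3 * q + 1], xw = w + up[3 * q + 2];
        if (!std::isfinite(xd) || !std::isfinite(xh) || !std::isfinite(xw)) continue;
        bool free_d = true, free_h = true, free_w = true;  // clamp kills the derivative
        if (padding == 0) {
          if (xd <= 0.0) { xd = 0.0; free_d = false; }
          if (xd >= D - 1) { xd = D - 1; free_d = false; }
          if (xh <= 0.0) { xh = 0.0; free_h = false; }
          if (xh >= H - 1) { xh = H - 1; free_h = false; }
          if (xw <= 0.0) { xw = 0.0; free_w = false; }
          if (xw >= W - 1) { xw = W - 1; free_w = false; }
        }
        int fd = (int)std::floor(xd), fh = (int)std::floor(xh), fw = (int)std::floor(xw);
        double td = xd - fd, th = xh - fh, tw = xw - fw;
        double dgd = 0.0, dgh = 0.0, dgw = 0.0;
        for (int cw = 0; cw < 2; ++cw)
          for (int ch = 0; ch < 2; ++ch)
            for (int cd = 0; cd < 2; ++cd) {
              int id = fd + cd, ih = fh + ch, iw = fw + cw;
              double wd_ = cd ? td : 1 - td, wh = ch ? th : 1 - th, ww = cw ? tw : 1 - tw;
              double val;
              bool inb = id >= 0 && id < D && ih >= 0 && ih < H && iw >= 0 && iw < W;
              if (padding == 0) {
                int jd = id < 0 ? 0 : (id >= D ? D - 1 : id);
                int jh = ih < 0 ? 0 : (ih >= H ? H - 1 : ih);
                int jw = iw < 0 ? 0 : (iw >= W ? W - 1 : iw);
                val = vp[jd + (size_t)D * (jh + (size_t)H * jw)];
                gvp[jd + (size_t)D * (jh + (size_t)H * jw)] += g * wd_ * wh * ww;
              } else {
                val = inb ? vp[id + (size_t)D * (ih + (size_t)H * iw)] : 0.0;
                if (inb) gvp[id + (size_t)D * (ih + (size_t)H * iw)] += g * wd_ * wh * ww;
              }
              dgd += (cd ? 1.0 : -1.0) * wh * ww * val;
              dgh += wd_ * (ch ? 1.0 : -1.0) * ww * val;
              dgw += wd_ * wh * (cw ? 1.0 : -1.0) * val;
            }
        if (free_d) gup[3 * q] = g * dgd;
        if (free_h) gup[3 * q + 1] = g * dgh;
        if (free_w) gup[3 * q + 2] = g * dgw;
      }
  gvol.attr("dim") = vd;
  gu.attr("dim") = IntegerVector::create(3, D, H, W);
  return List::create(_["gvol"] = gvol, _["gu"] = gu);
}

// Separable Gaussian blur on a (D,H,W) volume, replicate boundary.
// [[Rcpp::export(name = ".blur3d")]]
NumericVector blur3d(NumericVector x, double sigma) {
  IntegerVector xd = x.attr("dim");
  int D = xd[0], H = xd[1], W = xd[2];
  if (sigma <= 0) return clone(x);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += ker[i + r]; }
  for (double &kv : ker) kv /= s;
  std::vector<double> a(x.begin(), x.end()), b(a.size());
  int dims[3] = {D, H, W};
  size_t strides[3] = {1, (size_t)D, (size_t)D * H};
  for (int axis = 0; axis < 3; ++axis) {
    int n = dims[axis];
    size_t st = strides[axis];
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int d = 0; d < D; ++d) {
          size_t q = d + (size_t)D * (h + (size_t)H * w);
          int pos = axis == 0 ? d : (axis == 1 ? h : w);
          double acc = 0;
          for (int i = -r; i <= r; ++i) {
            int p = pos + i;
            p = p < 0 ? 0 : (p >= n ? n - 1 : p);
            acc += ker[i + r] * a[q + (p - pos) * (long)st];
          }
          b[q] = acc;
        }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = xd;
  return out;
}

// 2x2x2 average pooling (truncating odd trailing voxels), for MS-SSIM pyramids.
// [[Rcpp::export(name = ".downsample2_avg")]]
NumericVector downsample2_avg(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int D = xd[0], H = xd[1], W = xd[2];
  int D2 = D / 2, H2 = H / 2, W2 = W / 2;
  NumericVector y((size_t)D2 * H2 * W2);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int w = 0; w < W2; ++w)
    for (int h = 0; h < H2; ++h)
      for (int d = 0; d < D2; ++d) {
        double acc = 0;
        for (int cw = 0; cw < 2; ++cw)
          for (int ch = 0; ch < 2; ++ch)
            for (int cd = 0; cd < 2; ++cd)
              acc += xp[(2 * d + cd) + (size_t)D * ((2 * h + ch) + (size_t)H * (2 * w + cw))];
        yp[d + (size_t)D2 * (h + (size_t)H2 * w)] = acc / 8.0;
      }
  y.attr("dim") = IntegerVector::create(D2, H2, W2);
  return y;
}

// Trilinear upsampling by 2 (align-corners false, clamped borders),
// channel-first (C,D,H,W); used by the half-resolution field/template heads.
// [[Rcpp::export(name = ".upsample2lin_fwd")]]
NumericVector upsample2lin_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int C = xd[0], D = xd[1], H = xd[2], W = xd[3];
  int D2 = 2 * D, H2 = 2 * H, W2 = 2 * W;
  NumericVector y((size_t)C * D2 * H2 * W2);
  const double *xp = x.begin();
  double *yp = y.begin();
  auto prep = [](int o, int n, int &lo, int &hi, double &t) {
    double c = (o + 0.5) / 2.0 - 0.5;
    if (c < 0) c = 0;
    if (c > n - 1) c = n - 1;
    lo = (int)std::floor(c);
    hi = lo + 1 < n ? lo + 1 : lo;
    t = c - lo;
  };
  for (int w = 0; w < W2; ++w) {
    int wl, wh; double tw; prep(w, W, wl, wh, tw);
    for (int h = 0; h < H2; ++h) {
      int hl, hh; double th; prep(h, H, hl, hh, th);
      for (int d = 0; d < D2; ++d) {
        int dl, dh; double td; prep(d, D, dl, dh, td);
        double *dst = yp + (size_t)C * (d + (size_t)D2 * (h + (size_t)H2 * w));
        for (int c = 0; c < C; ++c) {
          auto at = [&](int dd, int hhh, int www) {
            return xp[c + (size_t)C * (dd + (size_t)D * (hhh + (size_t)H * www))];
          };
          double v =
            (1 - td) * (1 - th) * (1 - tw) * at(dl, hl, wl) +
            td * (1 - th) * (1 - tw) * at(dh, hl, wl) +
            (1 - td) * th * (1 - tw) * at(dl, hh, wl) +
            td * th * (1 - tw) * at(dh, hh, wl) +
            (1 - td) * (1 - th) * tw * at(dl, hl, wh) +
            td * (1 - th) * tw * at(dh, hl, wh) +
            (1 - td) * th * tw * at(dl, hh, wh) +
            td * th * tw * at(dh, hh, wh);
          dst[c] = v;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, D2, H2, W2);
  return y;
}

// [[Rcpp::export(name = ".upsample2lin_bwd")]]
NumericVector upsample2lin_bwd(NumericVector gy) {
  IntegerVector gd = gy.attr("dim");
  int C = gd[0], D2 = gd[1], H2 = gd[2], W2 = gd[3];
  int D = D2 / 2, H = H2 / 2, W = W2 / 2;
  NumericVector gx((size_t)C * D * H * W);
  const double *gp = gy.begin();
  double *xp = gx.begin();
  auto prep = [](int o, int n, int &lo, int &hi, double &t) {
    double c = (o + 0.5) / 2.0 - 0.5;
    if (c < 0) c = 0;
    if (c > n - 1) c = n - 1;
    lo = (int)std::floor(c);
    hi = lo + 1 < n ? lo + 1 : lo;
    t = c - lo;
  };
  for (int w = 0; w < W2; ++w) {
    int wl, wh; double tw; prep(w, W, wl, wh, tw);
    for (int h = 0; h < H2; ++h) {
      int hl, hh; double th; prep(h, H, hl, hh, th);
      for (int d = 0; d < D2; ++d) {
        int dl, dh; double td; prep(d, D, dl, dh, td);
        const double *src = gp + (size_t)C * (d + (size_t)D2 * (h + (size_t)H2 * w));
        for (int c = 0; c < C; ++c) {
          auto add = [&](int dd, int hhh, int www, double wt) {
            xp[c + (size_t)C * (dd + (size_t)D * (hhh + (size_t)H * www))] += wt * src[c];
          };
          add(dl, hl, wl, (1 - td) * (1 - th) * (1 - tw));
          add(dh, hl, wl, td * (1 - th) * (1 - tw));
          add(dl, hh, wl, (1 - td) * th * (1 - tw));
          add(dh, hh, wl, td * th * (1 - tw));
          add(dl, hl, wh, (1 - td) * (1 - th) * tw);
          add(dh, hl, wh, td * (1 - th) * tw);
          add(dl, hh, wh, (1 - td) * th * tw);
          add(dh, hh, wh, td * th * tw);
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(C, D, H, W);
  return gx;
}

// Displacement regularizer (mean convention) and its gradient in one pass.
// u is (3,D,H,W) voxel-unit displacements; with normalize != 0 each channel
// is first divided by its half grid extent, and the gradient is mapped back
// to voxel units by the chain rule. Forward differences, replicated edge.
// [[Rcpp::export(name = ".reg_terms_grad")]]
List reg_terms_grad(NumericVector u, double alpha, double beta, int normalize,
                    bool want_grad) {
  IntegerVector ud = u.attr("dim");
  int D = ud[1], H = ud[2], W = ud[3];
  size_t nvox = (size_t)D * H * W;
  double halfext[3] = {(D - 1) / 2.0, (H - 1) / 2.0, (W - 1) / 2.0};
  std::vector<double> un(u.begin(), u.end());
  if (normalize) {
    for (size_t q = 0; q < nvox; ++q)
      for (int c = 0; c < 3; ++c) un[3 * q + c] /= halfext[c];
  }
  double mag = 0.0, grd = 0.0;
  NumericVector g(want_grad ? u.size() : 0);
  double *gp = want_grad ? g.begin() : nullptr;
  const int strides[3] = {1, D, D * H};
  const int dims[3] = {D, H, W};
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        size_t q = d + (size_t)D * (h + (size_t)H * w);
        int pos[3] = {d, h, w};
        for (int c = 0; c < 3; ++c) {
          double v = un[3 * q + c];
          mag += v * v;
          if (want_grad) gp[3 * q + c] += 2.0 * alpha * v / (double)nvox;
          for (int a = 0; a < 3; ++a) {
            if (pos[a] + 1 >= dims[a]) continue;  // replicated edge: zero diff
            size_t q2 = q + strides[a];
            double dv = un[3 * q2 + c] - v;
            grd += dv * dv;
            if (want_grad) {
              gp[3 * q + c] -= 2.0 * beta * dv / (double)nvox;
              gp[3 * q2 + c] += 2.0 * beta * dv / (double)nvox;
            }
          }
        }
      }
  mag /= (double)nvox;
  grd /= (double)nvox;
  if (want_grad) {
    if (normalize) {
      for (size_t q = 0; q < nvox; ++q)
        for (int c = 0; c < 3; ++c) gp[3 * q + c] /= halfext[c];
    }
    g.attr("dim") = ud;
  }
  return List::create(_["magnitude"] = mag, _["gradient"] = grd,
                      _["total"] = alpha * mag + beta * grd, _["grad"] = g);
}
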