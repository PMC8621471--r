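// Core numerics for the learned regularizer r_eps(x) = sum_j sqrt(||g_j||^2
// + eps^2) - eps, where g is an l-layer complex convolutional feature
// extractor with a smoothed-ReLU activation applied separately to real and
// imaginary parts. Gradients follow the real-coordinate semantics: the
// "gradient" at a complex entry v is dS/dRe(v) + i dS/dIm(v), so the
// backward pass of a complex-linear convolution uses conjugated kernels.
//
// Feature maps are stored as separate real/imaginary planes (structure of
// arrays) so the kernel-tap inner loops vectorize.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Smoothed ReLU (quadratic blend on (-delta, delta)) and its derivative.
static inline double phi_s(double v, double d) {
  if (v <= -d) return 0.0;
  if (v >= d) return v;
  return v * v / (4.0 * d) + 0.5 * v + 0.25 * d;
}
static inline double phi_sp(double v, double d) {
  if (v <= -d) return 0.0;
  if (v >= d) return 1.0;
  return v / (2.0 * d) + 0.5;
}

// A multi-channel complex field: channel-major planes of h*w doubles.
struct Field {
  int h = 0, w = 0, c = 0;
  std::vector<double> re, im;
  void init(int h_, int w_, int c_) {
    h = h_; w = w_; c = c_;
    re.assign((size_t)h * w * c, 0.0);
    im.assign((size_t)h * w * c, 0.0);
  }
  inline double* rp(int ch) { return re.data() + (size_t)h * w * ch; }
  inline double* ip(int ch) { return im.data() + (size_t)h * w * ch; }
  inline const double* rp(int ch) const { return re.data() + (size_t)h * w * ch; }
  inline const double* ip(int ch) const { return im.data() + (size_t)h * w * ch; }
};

struct Layer {
  int kh, kw, cin, cout;
  std::vector<double> wre, wim; // kh x kw x cin x cout, column-major
  inline size_t idx(int p, int q, int ci, int co) const {
    return p + (size_t)kh * (q + (size_t)kw * (ci + (size_t)cin * co));
  }
};

static std::vector<Layer> unpack_weights(const List& W) {
  std::vector<Layer> layers;
  for (int l = 0; l < W.size(); ++l) {
    ComplexVector wv = W[l];
    IntegerVector d = wv.attr("dim");
    if (d.size() != 4) stop("kernel array must have dim (kh, kw, cin, cout)");
    Layer L;
    L.kh = d[0]; L.kw = d[1]; L.cin = d[2]; L.cout = d[3];
    if (L.kh % 2 == 0 || L.kw % 2 == 0) stop("kernel spatial size must be odd");
    L.wre.resize(wv.size());
    L.wim.resize(wv.size());
    for (int i = 0; i < wv.size(); ++i) {
      L.wre[i] = wv[i].r;
      L.wim[i] = wv[i].i;
      if (!std::isfinite(wv[i].r) || !std::isfinite(wv[i].i)) {
        stop("non-finite kernel weight");
      }
    }
    layers.push_back(std::move(L));
  }
  return layers;
}

// One kernel tap accumulated over the valid region:
// out[i, j] += k * in[i + dp, j + dq]  (complex k, zero padding).
static inline void tap_accum(const double* __restrict inr,
                             const double* __restrict ini,
                             double* __restrict outr,
                             double* __restrict outi,
                             int h, int w, int dp, int dq,
                             double kr, double ki) {
  const int i0 = dp > 0 ? 0 : -dp, i1 = dp > 0 ? h - dp : h;
  const int j0 = dq > 0 ? 0 : -dq, j1 = dq > 0 ? w - dq : w;
  if (i1 <= i0 || j1 <= j0) return;
  for (int j = j0; j < j1; ++j) {
    const double* __restrict ar = inr + (size_t)h * (j + dq) + (i0 + dp);
    const double* __restrict ai = ini + (size_t)h * (j + dq) + (i0 + dp);
    double* __restrict br = outr + (size_t)h * j + i0;
    double* __restrict bi = outi + (size_t)h * j + i0;
    const int n = i1 - i0;
    for (int i = 0; i < n; ++i) {
      br[i] += kr * ar[i] - ki * ai[i];
      bi[i] += kr * ai[i] + ki * ar[i];
    }
  }
}

// Correlation of two fields over one offset: sum_ij a[i + dp, j + dq] * b[i, j]
// with a conjugated (used for kernel gradients).
static inline void tap_corr(const double* __restrict ar,
                            const double* __restrict ai,
                            const double* __restrict br,
                            const double* __restrict bi,
                            int h, int w, int dp, int dq,
                            double* accr, double* acci) {
  const int i0 = dp > 0 ? 0 : -dp, i1 = dp > 0 ? h - dp : h;
  const int j0 = dq > 0 ? 0 : -dq, j1 = dq > 0 ? w - dq : w;
  double sr = 0.0, si = 0.0;
  for (int j = j0; j < j1; ++j) {
    const double* __restrict xr = ar + (size_t)h * (j + dq) + (i0 + dp);
    const double* __restrict xi = ai + (size_t)h * (j + dq) + (i0 + dp);
    const double* __restrict yr = br + (size_t)h * j + i0;
    const double* __restrict yi = bi + (size_t)h * j + i0;
    const int n = i1 - i0;
    for (int i = 0; i < n; ++i) {
      // conj(x) * y
      sr += xr[i] * yr[i] + xi[i] * yi[i];
      si += xr[i] * yi[i] - xi[i] * yr[i];
    }
  }
  *accr = sr;
  *acci = si;
}

// Same-size zero-padded complex convolution (CNN cross-correlation form).
static void conv_forward(const Field& in, const Layer& L, Field& out) {
  const int cy = (L.kh - 1) / 2, cx = (L.kw - 1) / 2;
  out.init(in.h, in.w, L.cout);
  for (int co = 0; co < L.cout; ++co)
    for (int ci = 0; ci < L.cin; ++ci)
      for (int q = 0; q < L.kw; ++q)
        for (int p = 0; p < L.kh; ++p) {
          const size_t k = L.idx(p, q, ci, co);
          tap_accum(in.rp(ci), in.ip(ci), out.rp(co), out.ip(co),
                    in.h, in.w, p - cy, q - cx, L.wre[k], L.wim[k]);
        }
}

// Adjoint under the real inner product: conjugated kernels, reversed
// offsets, swapped channel roles.
static void conv_backward_input(const Field& gout, const Layer& L,
                                Field& gin) {
  const int cy = (L.kh - 1) / 2, cx = (L.kw - 1) / 2;
  gin.init(gout.h, gout.w, L.cin);
  for (int co = 0; co < L.cout; ++co)
    for (int ci = 0; ci < L.cin; ++ci)
      for (int q = 0; q < L.kw; ++q)
        for (int p = 0; p < L.kh; ++p) {
          const size_t k = L.idx(p, q, ci, co);
          // out[i, j] consumed in[i + dp, j + dq]:
          // gin[i + dp, j + dq] += conj(k) * gout[i, j]
          tap_accum(gout.rp(co), gout.ip(co), gin.rp(ci), gin.ip(ci),
                    gout.h, gout.w, -(p - cy), -(q - cx), L.wre[k], -L.wim[k]);
        }
}

// Gradient wrt the kernel: correlation of the output gradient with the
// conjugated layer input.
static void conv_backward_weight(const Field& in, const Field& gout,
                                 const Layer& L, std::vector<double>& gwr,
                                 std::vector<double>& gwi) {
  const int cy = (L.kh - 1) / 2, cx = (L.kw - 1) / 2;
  gwr.assign(L.wre.size(), 0.0);
  gwi.assign(L.wre.size(), 0.0);
  for (int co = 0; co < L.cout; ++co)
    for (int ci = 0; ci < L.cin; ++ci)
      for (int q = 0; q < L.kw; ++q)
        for (int p = 0; p < L.kh; ++p) {
          const size_t k = L.idx(p, q, ci, co);
          tap_corr(in.rp(ci), in.ip(ci), gout.rp(co), gout.ip(co),
                   in.h, in.w, p - cy, q - cx, &gwr[k], &gwi[k]);
        }
}

static Field field_from_R(const ComplexVector& x, int h, int w, int c) {
  Field f;
  f.init(h, w, c);
  for (size_t i = 0; i < (size_t)x.size(); ++i) {
    f.re[i] = x[i].r;
    f.im[i] = x[i].i;
  }
  return f;
}

static ComplexVector field_to_R(const Field& f, IntegerVector dim) {
  ComplexVector out((size_t)f.h * f.w * f.c);
  for (size_t i = 0; i < (size_t)out.size(); ++i) {
    out[i].r = f.re[i];
    out[i].i = f.im[i];
  }
  out.attr("dim") = dim;
  return out;
}

// Run the extractor forward, keeping pre-activations and layer inputs.
static void g_forward_impl(const Field& x, const std::vector<Layer>& layers,
                           double delta, std::vector<Field>& inputs,
                           std::vector<Field>& pres, Field& g) {
  const int L = layers.size();
  inputs.resize(L);
  pres.resize(L > 1 ? L - 1 : 0);
  Field cur = x;
  for (int l = 0; l < L; ++l) {
    inputs[l] = cur;
    Field out;
    conv_forward(cur, layers[l], out);
    if (l < L - 1) {
      pres[l] = out;
      for (size_t i = 0; i < out.re.size(); ++i) {
        out.re[i] = phi_s(out.re[i], delta);
        out.im[i] = phi_s(out.im[i], delta);
      }
      cur = std::move(out);
    } else {
      g = std::move(out);
    }
  }
}

// [[Rcpp::export]]
ComplexVector cpp_complex_conv(ComplexVector x, ComplexVector w) {
  IntegerVector xd = x.hasAttribute("dim") ? (IntegerVector)x.attr("dim")
                                           : IntegerVector::create(0, 0);
  if (xd.size() == 2) xd = IntegerVector::create(xd[0], xd[1], 1);
  List W = List::create(w);
  std::vector<Layer> layers = unpack_weights(W);
  if (layers[0].cin != xd[2]) stop("shape mismatch: input channels");
  Field xf = field_from_R(x, xd[0], xd[1], xd[2]);
  Field out;
  conv_forward(xf, layers[0], out);
  return field_to_R(out, IntegerVector::create(xd[0], xd[1], layers[0].cout));
}

// [[Rcpp::export]]
ComplexVector cpp_g_forward(ComplexMatrix x, List W, double delta) {
  std::vector<Layer> layers = unpack_weights(W);
  std::vector<Field> inputs, pres;
  Field g, xf = field_from_R(ComplexVector(x), x.nrow(), x.ncol(), 1);
  g_forward_impl(xf, layers, delta, inputs, pres, g);
  return field_to_R(g, IntegerVector::create(x.nrow(), x.ncol(),
                                             layers.back().cout));
}

// [[Rcpp::export]]
double cpp_reg_value(ComplexMatrix x, List W, double delta, double eps) {
  std::vector<Layer> layers = unpack_weights(W);
  std::vector<Field> inputs, pres;
  Field g, xf = field_from_R(ComplexVector(x), x.nrow(), x.ncol(), 1);
  g_forward_impl(xf, layers, delta, inputs, pres, g);
  const int n = g.h * g.w;
  double val = 0.0;
  for (int j = 0; j < n; ++j) {
    double s2 = 0.0;
    for (int c = 0; c < g.c; ++c) {
      const double gr = g.rp(c)[j], gi = g.ip(c)[j];
      s2 += gr * gr + gi * gi;
    }
    val += std::sqrt(s2 + eps * eps) - eps;
  }
  return val;
}

// Value, gradient wrt x, and (optionally) gradient wrt every kernel of
// r_eps(x; W). Backward pass: outer derivative g_j / sqrt(||g_j||^2 + eps^2)
// pulled through conv transposes with phi-prime gates on both real and
// imaginary channels.
// [[Rcpp::export]]
List cpp_reg_backprop(ComplexMatrix x, List W, double delta, double eps,
                      bool want_w) {
  std::vector<Layer> layers = unpack_weights(W);
  const int L = layers.size();
  std::vector<Field> inputs, pres;
  Field g, xf = field_from_R(ComplexVector(x), x.nrow(), x.ncol(), 1);
  g_forward_impl(xf, layers, delta, inputs, pres, g);

  const int n = g.h * g.w;
  double val = 0.0;
  Field dg;
  dg.init(g.h, g.w, g.c);
  for (int j = 0; j < n; ++j) {
    double s2 = 0.0;
    for (int c = 0; c < g.c; ++c) {
      const double gr = g.rp(c)[j], gi = g.ip(c)[j];
      s2 += gr * gr + gi * gi;
    }
    const double root = std::sqrt(s2 + eps * eps);
    val += root - eps;
    for (int c = 0; c < g.c; ++c) {
      dg.rp(c)[j] = g.rp(c)[j] / root;
      dg.ip(c)[j] = g.ip(c)[j] / root;
    }
  }

  List gw_list(L);
  Field cur = std::move(dg);
  for (int l = L - 1; l >= 0; --l) {
    if (want_w) {
      std::vector<double> gwr, gwi;
      conv_backward_weight(inputs[l], cur, layers[l], gwr, gwi);
      ComplexVector gw(gwr.size());
      for (size_t i = 0; i < gwr.size(); ++i) {
        gw[i].r = gwr[i];
        gw[i].i = gwi[i];
      }
      gw.attr("dim") = IntegerVector::create(layers[l].kh, layers[l].kw,
                                             layers[l].cin, layers[l].cout);
      gw_list[l] = gw;
    }
    Field gin;
    conv_backward_input(cur, layers[l], gin);
    if (l > 0) {
      // Gate by the activation derivative at the previous pre-activation.
      const Field& pre = pres[l - 1];
      for (size_t i = 0; i < gin.re.size(); ++i) {
        gin.re[i] *= phi_sp(pre.re[i], delta);
        gin.im[i] *= phi_sp(pre.im[i], delta);
      }
    }
    cur = std::move(gin);
  }

  ComplexVector gx = field_to_R(cur, IntegerVector::create(x.nrow(), x.ncol()));
  List out = List::create(Named("value") = val, Named("grad_x") = gx);
  if (want_w) out["grad_w"] = gw_list;
  return out;
}
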