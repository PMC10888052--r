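// Low-level tensor primitives for the segmentation network.
// Layout convention: volumes are R arrays with dim c(H, W, D, C) (channel-last,
// column-major, batch size 1). Convolutions are stride-1, zero-padded "same",
// expressed as cross-correlations (the deep-learning convention).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static inline int idx4(int h, int w, int d, int c, int H, int W, int D) {
  return h + H * (w + W * (d + D * c));
}

// [[Rcpp::export]]
NumericVector conv3d_fw(NumericVector x, NumericVector wt,
                        Nullable<NumericVector> bias, int groups) {
  IntegerVector xd = x.attr("dim");   // H W D Cin
  IntegerVector wd = wt.attr("dim");  // k k k Cin/g Cout
  const int H = xd[0], W = xd[1], D = xd[2], Cin = xd[3];
  const int k = wd[0], Cg = wd[3], Cout = wd[4];
  if (Cin / groups != Cg) stop("conv3d_fw: channel/group mismatch");
  const int p = (k - 1) / 2;
  NumericVector y(static_cast<R_xlen_t>(H) * W * D * Cout);
  y.attr("dim") = IntegerVector::create(H, W, D, Cout);
  const double *xp = x.begin(), *wp = wt.begin();
  double *yp = y.begin();
  const int cout_per_g = Cout / groups;
  for (int oc = 0; oc < Cout; ++oc) {
    const int g = oc / cout_per_g;
    for (int icl = 0; icl < Cg; ++icl) {
      const int ic = g * Cg + icl;
      const double *xc = xp + static_cast<R_xlen_t>(H) * W * D * ic;
      double *yc = yp + static_cast<R_xlen_t>(H) * W * D * oc;
      for (int kz = 0; kz < k; ++kz)
        for (int ky = 0; ky < k; ++ky)
          for (int kx = 0; kx < k; ++kx) {
            const double wv =
                wp[kx + k * (ky + k * (kz + k * (icl + Cg * oc)))];
            if (wv == 0.0) continue;
            const int dh = kx - p, dw = ky - p, dd = kz - p;
            const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
            const int d0 = std::max(0, -dd), d1 = std::min(D, D - dd);
            for (int d = d0; d < d1; ++d)
              for (int w = w0; w < w1; ++w) {
                const double *xrow = xc + (h0 + dh) + H * ((w + dw) + W * (d + dd));
                double *yrow = yc + h0 + H * (w + W * d);
                for (int h = 0; h < h1 - h0; ++h) yrow[h] += wv * xrow[h];
              }
          }
    }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int oc = 0; oc < Cout; ++oc) {
      double *yc = yp + static_cast<R_xlen_t>(H) * W * D * oc;
      const double bv = b[oc];
      const R_xlen_t n = static_cast<R_xlen_t>(H) * W * D;
      for (R_xlen_t i = 0; i < n; ++i) yc[i] += bv;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_bw(NumericVector x, NumericVector wt, NumericVector gy,
               int groups, bool has_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = wt.attr("dim");
  const int H = xd[0], W = xd[1], D = xd[2], Cin = xd[3];
  const int k = wd[0], Cg = wd[3], Cout = wd[4];
  const int p = (k - 1) / 2;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(wt.size());
  gw.attr("dim") = wd;
  const double *xp = x.begin(), *wp = wt.begin(), *gyp = gy.begin();
  double *gxp = gx.begin(), *gwp = gw.begin();
  const int cout_per_g = Cout / groups;
  for (int oc = 0; oc < Cout; ++oc) {
    const int g = oc / cout_per_g;
    const double *gyc = gyp + static_cast<R_xlen_t>(H) * W * D * oc;
    for (int icl = 0; icl < Cg; ++icl) {
      const int ic = g * Cg + icl;
      const double *xc = xp + static_cast<R_xlen_t>(H) * W * D * ic;
      double *gxc = gxp + static_cast<R_xlen_t>(H) * W * D * ic;
      for (int kz = 0; kz < k; ++kz)
        for (int ky = 0; ky < k; ++ky)
          for (int kx = 0; kx < k; ++kx) {
            const R_xlen_t widx = kx + k * (ky + k * (kz + k * (icl + Cg * oc)));
            const double wv = wp[widx];
            const int dh = kx - p, dw = ky - p, dd = kz - p;
            const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
            const int d0 = std::max(0, -dd), d1 = std::min(D, D - dd);
            double acc = 0.0;
            for (int d = d0; d < d1; ++d)
              for (int w = w0; w < w1; ++w) {
                const double *xrow = xc + (h0 + dh) + H * ((w + dw) + W * (d + dd));
                const double *grow = gyc + h0 + H * (w + W * d);
                double *gxrow = gxc + (h0 + dh) + H * ((w + dw) + W * (d + dd));
                for (int h = 0; h < h1 - h0; ++h) {
                  acc += grow[h] * xrow[h];
                  gxrow[h] += wv * grow[h];
                }
              }
            gwp[widx] += acc;
          }
    }
  }
  NumericVector gb;
  if (has_bias) {
    gb = NumericVector(Cout);
    for (int oc = 0; oc < Cout; ++oc) {
      const double *gyc = gyp + static_cast<R_xlen_t>(H) * W * D * oc;
      double acc = 0.0;
      const R_xlen_t n = static_cast<R_xlen_t>(H) * W * D;
      for (R_xlen_t i = 0; i < n; ++i) acc += gyc[i];
      gb[oc] = acc;
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

struct LinIdx {
  // precomputed 1-axis interpolation: low index, high index, high weight
  std::vector<int> lo, hi;
  std::vector<double> t;
};

static LinIdx axis_map(int out_n, int in_n) {
  LinIdx m;
  m.lo.resize(out_n);
  m.hi.resize(out_n);
  m.t.resize(out_n);
  const double scale = static_cast<double>(in_n) / out_n;
  for (int o = 0; o < out_n; ++o) {
    double src = (o + 0.5) * scale - 0.5;  // half-pixel centers
    if (src < 0) src = 0;
    if (src > in_n - 1) src = in_n - 1;
    const int lo = static_cast<int>(std::floor(src));
    const int hi = std::min(lo + 1, in_n - 1);
    m.lo[o] = lo;
    m.hi[o] = hi;
    m.t[o] = src - lo;
  }
  return m;
}

// [[Rcpp::export]]
NumericVector resize3d_fw(NumericVector x, int oh, int ow, int od) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], D = xd[2], C = xd[3];
  LinIdx mh = axis_map(oh, H), mw = axis_map(ow, W), md = axis_map(od, D);
  NumericVector y(static_cast<R_xlen_t>(oh) * ow * od * C);
  y.attr("dim") = IntegerVector::create(oh, ow, od, C);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = xp + static_cast<R_xlen_t>(H) * W * D * c;
    double *yc = yp + static_cast<R_xlen_t>(oh) * ow * od * c;
    for (int d = 0; d < od; ++d)
      for (int w = 0; w < ow; ++w)
        for (int h = 0; h < oh; ++h) {
          const double th = mh.t[h], tw = mw.t[w], td = md.t[d];
          double v = 0.0;
          for (int bd = 0; bd < 2; ++bd)
            for (int bw = 0; bw < 2; ++bw)
              for (int bh = 0; bh < 2; ++bh) {
                const double wgt = (bh ? th : 1 - th) * (bw ? tw : 1 - tw) *
                                   (bd ? td : 1 - td);
                if (wgt == 0.0) continue;
                v += wgt * xc[idx4(bh ? mh.hi[h] : mh.lo[h],
                                   bw ? mw.hi[w] : mw.lo[w],
                                   bd ? md.hi[d] : md.lo[d], 0, H, W, D)];
              }
          yc[h + oh * (w + ow * d)] = v;
        }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector resize3d_bw(NumericVector gy, int ih, int iw, int id) {
  IntegerVector gd = gy.attr("dim");
  const int oh = gd[0], ow = gd[1], od = gd[2], C = gd[3];
  LinIdx mh = axis_map(oh, ih), mw = axis_map(ow, iw), md = axis_map(od, id);
  NumericVector gx(static_cast<R_xlen_t>(ih) * iw * id * C);
  gx.attr("dim") = IntegerVector::create(ih, iw, id, C);
  const double *gp = gy.begin();
  double *xp = gx.begin();
  for (int c = 0; c < C; ++c) {
    double *xc = xp + static_cast<R_xlen_t>(ih) * iw * id * c;
    const double *gc = gp + static_cast<R_xlen_t>(oh) * ow * od * c;
    for (int d = 0; d < od; ++d)
      for (int w = 0; w < ow; ++w)
        for (int h = 0; h < oh; ++h) {
          const double g = gc[h + oh * (w + ow * d)];
          if (g == 0.0) continue;
          const double th = mh.t[h], tw = mw.t[w], td = md.t[d];
          for (int bd = 0; bd < 2; ++bd)
            for (int bw = 0; bw < 2; ++bw)
              for (int bh = 0; bh < 2; ++bh) {
                const double wgt = (bh ? th : 1 - th) * (bw ? tw : 1 - tw) *
                                   (bd ? td : 1 - td);
                if (wgt == 0.0) continue;
                xc[idx4(bh ? mh.hi[h] : mh.lo[h], bw ? mw.hi[w] : mw.lo[w],
                        bd ? md.hi[d] : md.lo[d], 0, ih, iw, id)] += wgt * g;
              }
        }
  }
  return gx;
}

// 1D squared-distance transform (lower envelope of parabolas), anisotropic.
static void dt1d(const std::vector<double> &f, std::vector<double> &out,
                 double step) {
  const int n = static_cast<int>(f.size());
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int q = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double s2 = step * step;
  for (int i = 1; i < n; ++i) {
    double s;
    while (true) {
      s = ((f[i] + s2 * i * i) - (f[v[q]] + s2 * v[q] * v[q])) /
          (2.0 * s2 * (i - v[q]));
      if (s <= z[q]) {
        --q;
      } else {
        break;
      }
    }
    ++q;
    v[q] = i;
    z[q] = s;
    z[q + 1] = INF;
  }
  q = 0;
  for (int i = 0; i < n; ++i) {
    while (z[q + 1] < i) ++q;
    const double d = static_cast<double>(i - v[q]);
    out[i] = s2 * d * d + f[v[q]];
  }
}

// Euclidean distance transform: distance from every voxel to the nearest
// nonzero voxel of `mask`, with anisotropic spacing. Returns +Inf everywhere
// if the mask is empty.
// [[Rcpp::export]]
NumericVector edt3d(LogicalVector mask, double sx, double sy, double sz) {
  IntegerVector md = mask.attr("dim");
  const int H = md[0], W = md[1], D = md[2];
  bool any = false;
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    if (mask[i]) { any = true; break; }
  NumericVector out(mask.size());
  out.attr("dim") = md;
  if (!any) {
    std::fill(out.begin(), out.end(),
              std::numeric_limits<double>::infinity());
    return out;
  }
  // large finite stand-in for +Inf keeps the parabola intersections NaN-free
  const double BIG = 1e20;
  std::vector<double> g(static_cast<size_t>(H) * W * D);
  for (R_xlen_t i = 0; i < mask.size(); ++i) g[i] = mask[i] ? 0.0 : BIG;
  std::vector<double> f, o;
  // axis H (spacing sx)
  f.resize(H);
  o.resize(H);
  for (int d = 0; d < D; ++d)
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) f[h] = g[h + H * (w + W * d)];
      dt1d(f, o, sx);
      for (int h = 0; h < H; ++h) g[h + H * (w + W * d)] = o[h];
    }
  // axis W (spacing sy)
  f.resize(W);
  o.resize(W);
  for (int d = 0; d < D; ++d)
    for (int h = 0; h < H; ++h) {
      for (int w = 0; w < W; ++w) f[w] = g[h + H * (w + W * d)];
      dt1d(f, o, sy);
      for (int w = 0; w < W; ++w) g[h + H * (w + W * d)] = o[w];
    }
  // axis D (spacing sz)
  f.resize(D);
  o.resize(D);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      for (int d = 0; d < D; ++d) f[d] = g[h + H * (w + W * d)];
      dt1d(f, o, sz);
      for (int d = 0; d < D; ++d) g[h + H * (w + W * d)] = o[d];
    }
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = std::sqrt(g[i]);
  return out;
}
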