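#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fan-beam conventions (shared by every kernel so that squeezed and full
// sinogram paths sample rays identically):
//  - world: isocenter origin, x right, y up, lengths in mm
//  - view angle beta: source azimuth, counter-clockwise from +y
//  - flat equidistant detector at distance sdd from the source, perpendicular
//    to the central ray; detector sample k sits at u_k = (k - (D-1)/2) * pitch
//  - image pixel (r, c) (0-based, row-major, row 0 on top) has world center
//    x = ox + c * spacing, y = oy - r * spacing

struct View {
  double sx, sy;  // source position
  double tx, ty;  // unit vector source -> isocenter (central ray)
  double ux, uy;  // unit vector along the detector
};

static inline View make_view(double beta, double sid) {
  View v;
  const double sb = std::sin(beta), cb = std::cos(beta);
  v.sx = -sid * sb; v.sy = sid * cb;
  v.tx = sb;        v.ty = -cb;
  v.ux = cb;        v.uy = sb;
  return v;
}

// Continuous (0-based) detector index hit by the ray from the source through
// world point (px, py); L2 receives the squared source-to-point distance.
static inline double project_index(const View& v, double sdd, double pitch,
                                   int ndet, double px, double py, double& L2) {
  const double dx = px - v.sx, dy = py - v.sy;
  const double t = dx * v.tx + dy * v.ty;
  const double u = dx * v.ux + dy * v.uy;
  L2 = dx * dx + dy * dy;
  return (sdd * u / t) / pitch + 0.5 * (ndet - 1);
}

// Orthonormal sinusoidal basis on [-1, 1]:
// PE(x) = [1, sqrt2*cos(pi x), sqrt2*sin(pi x), ..., sqrt2*cos(n pi x), sqrt2*sin(n pi x)]
static inline void pe_fill(double x, int n, double* out) {
  const double s2 = M_SQRT2;
  out[0] = 1.0;
  for (int k = 1; k <= n; ++k) {
    out[2 * k - 1] = s2 * std::cos(k * M_PI * x);
    out[2 * k]     = s2 * std::sin(k * M_PI * x);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericMatrix img, double spacing,
                                  NumericVector angles, double sid, double sdd,
                                  double pitch, int ndet, double step_frac) {
  const int ny = img.nrow(), nx = img.ncol(), nv = angles.size();
  NumericMatrix sino(nv, ndet);
  const double h = step_frac * spacing;
  // march only inside a bounding circle of the pixel grid
  const double rimg = 0.5 * std::sqrt((double)nx * nx + (double)ny * ny) * spacing + spacing;
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);

  for (int i = 0; i < nv; ++i) {
    const View v = make_view(angles[i], sid);
    for (int k = 0; k < ndet; ++k) {
      const double uk = (k - 0.5 * (ndet - 1)) * pitch;
      // detector cell center
      const double px = v.sx + sdd * v.tx + uk * v.ux;
      const double py = v.sy + sdd * v.ty + uk * v.uy;
      double dx = px - v.sx, dy = py - v.sy;
      const double len = std::sqrt(dx * dx + dy * dy);
      dx /= len; dy /= len;
      // ray-circle intersection |S + t d| = rimg
      const double b = v.sx * dx + v.sy * dy;
      const double c = v.sx * v.sx + v.sy * v.sy - rimg * rimg;
      const double disc = b * b - c;
      if (disc <= 0) { sino(i, k) = 0.0; continue; }
      const double t0 = -b - std::sqrt(disc), t1 = -b + std::sqrt(disc);
      double acc = 0.0;
      for (double t = t0 + 0.5 * h; t < t1; t += h) {
        const double wx = v.sx + t * dx, wy = v.sy + t * dy;
        // bilinear sample, zero outside the grid
        const double col = wx / spacing + cx;
        const double row = cy - wy / spacing;
        const int c0 = (int)std::floor(col), r0 = (int)std::floor(row);
        if (c0 < -1 || c0 > nx - 1 || r0 < -1 || r0 > ny - 1) continue;
        const double fc = col - c0, fr = row - r0;
        double val = 0.0;
        const bool cok0 = c0 >= 0 && c0 < nx, cok1 = c0 + 1 >= 0 && c0 + 1 < nx;
        const bool rok0 = r0 >= 0 && r0 < ny, rok1 = r0 + 1 >= 0 && r0 + 1 < ny;
        if (rok0 && cok0) val += (1 - fr) * (1 - fc) * img(r0, c0);
        if (rok0 && cok1) val += (1 - fr) * fc * img(r0, c0 + 1);
        if (rok1 && cok0) val += fr * (1 - fc) * img(r0 + 1, c0);
        if (rok1 && cok1) val += fr * fc * img(r0 + 1, c0 + 1);
        acc += val;
      }
      sino(i, k) = acc * h;
    }
  }
  return sino;
}

// Classical FBP back-projection (Eq.-3-style cross-weighted linear
// interpolation): y(x_q) = (pi/N) * sid^2 * sum_i (1/L_iq^2) *
//                          (l_i0 * z_i1 + l_i1 * z_i0) / l_i
// [[Rcpp::export]]
List cpp_backproject_fbp(NumericMatrix z, NumericVector angles, double sid,
                         double sdd, double pitch, int H, int W,
                         double spacing, double ox, double oy) {
  const int nv = angles.size(), ndet = z.ncol();
  NumericMatrix img(H, W);
  IntegerMatrix nmiss(H, W);
  const double scale = (M_PI / nv) * sid * sid;
  for (int i = 0; i < nv; ++i) {
    const View v = make_view(angles[i], sid);
    for (int r = 0; r < H; ++r) {
      const double py = oy - r * spacing;
      for (int c = 0; c < W; ++c) {
        const double px = ox + c * spacing;
        double L2;
        const double t = project_index(v, sdd, pitch, ndet, px, py, L2);
        const int k0 = (int)std::floor(t);
        if (k0 < 0 || k0 + 1 > ndet - 1) { nmiss(r, c) += 1; continue; }
        const double f = t - k0;  // l_i0 in detector-pitch units
        img(r, c) += (f * z(i, k0 + 1) + (1.0 - f) * z(i, k0)) / L2;
      }
    }
  }
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) img(r, c) *= scale;
  return List::create(_["image"] = img, _["n_outside"] = nmiss);
}

// CRET back-projection (FBP term + sinusoidal-decoder term) reading a
// squeezed sinogram. zsq is N x d; zstar is an N x d x nb array (may have
// length 0 for the plain-FBP path); win_off[i] is the original detector index
// of squeezed column 0 for view i.
// [[Rcpp::export]]
List cpp_cret_backproject(NumericMatrix zsq, NumericVector zstar, int nbasis,
                          IntegerVector win_off, NumericVector angles,
                          double sid, double sdd, double pitch, int ndet,
                          int H, int W, double spacing, double ox, double oy) {
  const int nv = angles.size(), d = zsq.ncol();
  const bool feat = zstar.size() > 0;
  const int n = (nbasis - 1) / 2;
  if (feat && zstar.size() != (R_xlen_t)nv * d * nbasis)
    stop("zstar length does not match N x d x (2n+1)");
  NumericMatrix img(H, W);
  IntegerMatrix nmiss(H, W);
  const double scale = (M_PI / nv) * sid * sid;
  std::vector<double> pe0(nbasis), pe1(nbasis);
  const double* zs = feat ? REAL(zstar) : nullptr;

  for (int i = 0; i < nv; ++i) {
    const View v = make_view(angles[i], sid);
    for (int r = 0; r < H; ++r) {
      const double py = oy - r * spacing;
      for (int c = 0; c < W; ++c) {
        const double px = ox + c * spacing;
        double L2;
        const double t = project_index(v, sdd, pitch, ndet, px, py, L2);
        const double col = t - win_off[i];
        const int k0 = (int)std::floor(col);
        if (k0 < 0 || k0 + 1 > d - 1) { nmiss(r, c) += 1; continue; }
        const double f = col - k0;
        double val = f * zsq(i, k0 + 1) + (1.0 - f) * zsq(i, k0);
        if (feat) {
          // normalized offsets in detector-pitch units:
          // d0 = x_iq - x_i0 in [0,1], d1 = x_iq - x_i1 in [-1,0]
          pe_fill(f, n, pe0.data());
          pe_fill(f - 1.0, n, pe1.data());
          double f0 = 0.0, f1 = 0.0;
          // column-major layout: zs[i + nv*(k + d*b)]
          for (int b = 0; b < nbasis; ++b) {
            f0 += zs[i + (R_xlen_t)nv * (k0 + (R_xlen_t)d * b)] * pe0[b];
            f1 += zs[i + (R_xlen_t)nv * (k0 + 1 + (R_xlen_t)d * b)] * pe1[b];
          }
          val += f * f1 + (1.0 - f) * f0;
        }
        img(r, c) += val / L2;
      }
    }
  }
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) img(r, c) *= scale;
  return List::create(_["image"] = img, _["n_outside"] = nmiss);
}

// Adjoint of the zstar -> image map of cpp_cret_backproject: accumulates
// d(loss)/d(zstar) from d(loss)/d(image). Geometry arguments must match the
// forward call exactly.
// [[Rcpp::export]]
NumericVector cpp_cret_backproject_grad(NumericMatrix gy, int nv, int d,
                                        int nbasis, IntegerVector win_off,
                                        NumericVector angles, double sid,
                                        double sdd, double pitch, int ndet,
                                        double spacing, double ox, double oy) {
  const int H = gy.nrow(), W = gy.ncol();
  const int n = (nbasis - 1) / 2;
  NumericVector grad((R_xlen_t)nv * d * nbasis);
  grad.attr("dim") = IntegerVector::create(nv, d, nbasis);
  double* g = REAL(grad);
  const double scale = (M_PI / nv) * sid * sid;
  std::vector<double> pe0(nbasis), pe1(nbasis);

  for (int i = 0; i < nv; ++i) {
    const View v = make_view(angles[i], sid);
    for (int r = 0; r < H; ++r) {
      const double py = oy - r * spacing;
      for (int c = 0; c < W; ++c) {
        const double gval = gy(r, c);
        if (gval == 0.0) continue;
        const double px = ox + c * spacing;
        double L2;
        const double t = project_index(v, sdd, pitch, ndet, px, py, L2);
        const double col = t - win_off[i];
        const int k0 = (int)std::floor(col);
        if (k0 < 0 || k0 + 1 > d - 1) continue;
        const double f = col - k0;
        pe_fill(f, n, pe0.data());
        pe_fill(f - 1.0, n, pe1.data());
        const double w = gval * scale / L2;
        for (int b = 0; b < nbasis; ++b) {
          g[i + (R_xlen_t)nv * (k0 + (R_xlen_t)d * b)]     += w * (1.0 - f) * pe0[b];
          g[i + (R_xlen_t)nv * (k0 + 1 + (R_xlen_t)d * b)] += w * f * pe1[b];
        }
      }
    }
  }
  return grad;
}

// ---- small dense 2D cross-correlation layers ("conv" in the deep-learning
// sense), stride 1, zero "same" padding; used by the tiny encoder/restorator.
// x: H x W x Cin, w: kh x kw x Cin x Cout, b: Cout. All column-major R arrays.

static inline void conv_dims(SEXP a, int dims[3]) {
  IntegerVector d = as<IntegerVector>(Rf_getAttrib(a, R_DimSymbol));
  if (d.size() != 3) stop("expected a 3-d array");
  dims[0] = d[0]; dims[1] = d[1]; dims[2] = d[2];
}

// Shift-and-add evaluation: for each weight tap (ki, kj, ci, co) the output
// plane co accumulates w * x shifted by (ki - ph, kj - pw) in plane ci, with
// the row/column ranges clipped at the borders (zero padding). Inner loops
// run over contiguous image columns so they vectorize.
// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  int xd[3]; conv_dims(x, xd);
  IntegerVector wd = as<IntegerVector>(Rf_getAttrib(w, R_DimSymbol));
  if (wd.size() != 4) stop("expected a 4-d weight array");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int kh = wd[0], kw = wd[1], wcin = wd[2], Cout = wd[3];
  if (wcin != Cin) stop("input channel mismatch");
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector y((R_xlen_t)H * W * Cout);
  y.attr("dim") = IntegerVector::create(H, W, Cout);
  const double* X = REAL(x); const double* Wt = REAL(w); double* Y = REAL(y);
  for (int co = 0; co < Cout; ++co) {
    double* yplane = Y + (R_xlen_t)H * W * co;
    const double bias = b[co];
    for (R_xlen_t k = 0; k < (R_xlen_t)H * W; ++k) yplane[k] = bias;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xplane = X + (R_xlen_t)H * W * ci;
      for (int kj = 0; kj < kw; ++kj) {
        const int dj = kj - pw;
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int ki = 0; ki < kh; ++ki) {
          const int di = ki - ph;
          const double wv = Wt[ki + (R_xlen_t)kh * (kj + (R_xlen_t)kw * (ci + (R_xlen_t)Cin * co))];
          if (wv == 0.0) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int j = j0; j < j1; ++j) {
            double* yc = yplane + (R_xlen_t)H * j;
            const double* xc = xplane + (R_xlen_t)H * (j + dj) + di;
            for (int i = i0; i < i1; ++i) yc[i] += wv * xc[i];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy) {
  int xd[3]; conv_dims(x, xd);
  IntegerVector wd = as<IntegerVector>(Rf_getAttrib(w, R_DimSymbol));
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector gx((R_xlen_t)H * W * Cin);
  gx.attr("dim") = IntegerVector::create(H, W, Cin);
  NumericVector gw((R_xlen_t)kh * kw * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  NumericVector gb(Cout);
  const double* X = REAL(x); const double* Wt = REAL(w); const double* GY = REAL(gy);
  double* GX = REAL(gx); double* GW = REAL(gw); double* GB = REAL(gb);
  for (int co = 0; co < Cout; ++co) {
    const double* gplane = GY + (R_xlen_t)H * W * co;
    double acc_b = 0.0;
    for (R_xlen_t k = 0; k < (R_xlen_t)H * W; ++k) acc_b += gplane[k];
    GB[co] = acc_b;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xplane = X + (R_xlen_t)H * W * ci;
      double* gxplane = GX + (R_xlen_t)H * W * ci;
      for (int kj = 0; kj < kw; ++kj) {
        const int dj = kj - pw;
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int ki = 0; ki < kh; ++ki) {
          const int di = ki - ph;
          const double wv = Wt[ki + (R_xlen_t)kh * (kj + (R_xlen_t)kw * (ci + (R_xlen_t)Cin * co))];
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          double acc_w = 0.0;
          for (int j = j0; j < j1; ++j) {
            const double* gc = gplane + (R_xlen_t)H * j;
            const double* xc = xplane + (R_xlen_t)H * (j + dj) + di;
            double* gxc = gxplane + (R_xlen_t)H * (j + dj) + di;
            for (int i = i0; i < i1; ++i) {
              acc_w += gc[i] * xc[i];
              gxc[i] += wv * gc[i];
            }
          }
          GW[ki + (R_xlen_t)kh * (kj + (R_xlen_t)kw * (ci + (R_xlen_t)Cin * co))] = acc_w;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
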