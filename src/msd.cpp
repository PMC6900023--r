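#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Mixed-scale dense network internals.
//
// Parameter vector layout for a network of depth d (width 1, 1 input channel,
// 2 output classes), all offsets 0-based:
//   [0, 9*d*(d+1)/2)                       3x3 kernels h_ij, layer i = 1..d,
//                                          source map j = 0..i-1, row-major
//   [K, K + d)                             hidden biases b_i
//   [W, W + 2*(d+1))                       output weights w_ci, c-major
//   [B, B + 2)                             output biases b_c
// Class index 0 = background, 1 = bone.
// ---------------------------------------------------------------------------

// Mirror about the border pixel without duplicating it (…,2,1,0,1,2,…),
// folding repeatedly so any integer index is legal.
static inline int reflect_index(int x, int n) {
  if (n == 1) return 0;
  const int period = 2 * (n - 1);
  x %= period;
  if (x < 0) x += period;
  if (x >= n) x = period - x;
  return x;
}

static inline int kernel_offset(int i, int j) {
  // kernels of layers 1..i-1 occupy 9 * (1 + 2 + ... + (i-1)) slots
  return 9 * ((i - 1) * i / 2 + j);
}

struct Layout {
  int d, K, W, B, total;
  explicit Layout(int depth) : d(depth) {
    K = 9 * depth * (depth + 1) / 2;
    W = K + depth;
    B = W + 2 * (depth + 1);
    total = B + 2;
  }
};

// out[r,c] += or = sum_{a,b} ker[3a+b] * in[reflect(r+s(a-1)), reflect(c+s(b-1))]
static void dilated_conv_acc(const double* in, int h, int w,
                             const double* ker, int s, double* out,
                             bool accumulate) {
  for (int c = 0; c < w; ++c) {
    int cc[3] = { reflect_index(c - s, w), c, reflect_index(c + s, w) };
    for (int r = 0; r < h; ++r) {
      int rr[3] = { reflect_index(r - s, h), r, reflect_index(r + s, h) };
      double acc = accumulate ? out[r + c * h] : 0.0;
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          acc += ker[a * 3 + b] * in[rr[a] + cc[b] * h];
      out[r + c * h] = acc;
    }
  }
}

// Adjoint of dilated_conv_acc: scatter grad_out back through the same taps.
static void dilated_conv_adjoint(const double* gout, int h, int w,
                                 const double* ker, int s, double* gin) {
  for (int c = 0; c < w; ++c) {
    int cc[3] = { reflect_index(c - s, w), c, reflect_index(c + s, w) };
    for (int r = 0; r < h; ++r) {
      int rr[3] = { reflect_index(r - s, h), r, reflect_index(r + s, h) };
      const double g = gout[r + c * h];
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          gin[rr[a] + cc[b] * h] += ker[a * 3 + b] * g;
    }
  }
}

// Kernel gradient: gker[a,b] = sum_{r,c} gout[r,c] * in[reflect(r+s(a-1)), reflect(c+s(b-1))]
static void dilated_conv_kernel_grad(const double* gout, const double* in,
                                     int h, int w, int s, double* gker) {
  for (int c = 0; c < w; ++c) {
    int cc[3] = { reflect_index(c - s, w), c, reflect_index(c + s, w) };
    for (int r = 0; r < h; ++r) {
      int rr[3] = { reflect_index(r - s, h), r, reflect_index(r + s, h) };
      const double g = gout[r + c * h];
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          gker[a * 3 + b] += g * in[rr[a] + cc[b] * h];
    }
  }
}

static inline int dilation_at(int i, int cycle) {
  return ((i - 1) % cycle) + 1;
}

// Forward pass. stack must have room for (d+1)*h*w doubles; prob for 2*h*w.
static void msd_forward_impl(const double* x, int h, int w,
                             const double* par, int d, int cycle,
                             double* stack, double* prob) {
  const Layout L(d);
  const int npx = h * w;
  std::copy(x, x + npx, stack); // z_0
  for (int i = 1; i <= d; ++i) {
    const int s = dilation_at(i, cycle);
    double* zi = stack + (size_t)i * npx;
    std::fill(zi, zi + npx, 0.0);
    for (int j = 0; j < i; ++j)
      dilated_conv_acc(stack + (size_t)j * npx, h, w,
                       par + kernel_offset(i, j), s, zi, true);
    const double bi = par[L.K + (i - 1)];
    for (int p = 0; p < npx; ++p) {
      double v = zi[p] + bi;
      zi[p] = v > 0.0 ? v : 0.0;
    }
  }
  // 1x1 output convolution + softmax
  const double* w0 = par + L.W;            // background weights
  const double* w1 = par + L.W + (d + 1);  // bone weights
  const double b0 = par[L.B], b1 = par[L.B + 1];
  for (int p = 0; p < npx; ++p) {
    double l0 = b0, l1 = b1;
    for (int i = 0; i <= d; ++i) {
      const double z = stack[(size_t)i * npx + p];
      l0 += w0[i] * z;
      l1 += w1[i] * z;
    }
    const double m = l0 > l1 ? l0 : l1;
    const double e0 = std::exp(l0 - m), e1 = std::exp(l1 - m);
    const double Z = e0 + e1;
    prob[p] = e0 / Z;        // background
    prob[npx + p] = e1 / Z;  // bone
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_dilated_conv(NumericMatrix map, NumericMatrix kernel, int s) {
  const int h = map.nrow(), w = map.ncol();
  // kernel arrives as a 3x3 R matrix (row index = dr, col index = dc);
  // repack row-major
  double ker[9];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      ker[a * 3 + b] = kernel(a, b);
  NumericMatrix out(h, w);
  dilated_conv_acc(REAL(map), h, w, ker, s, REAL(out), false);
  return out;
}

// [[Rcpp::export]]
List cpp_msd_forward(NumericMatrix slice, NumericVector params, int depth,
                     int cycle, bool keep_stack) {
  const int h = slice.nrow(), w = slice.ncol();
  const int npx = h * w;
  std::vector<double> stack((size_t)(depth + 1) * npx);
  NumericVector prob(2 * npx);
  msd_forward_impl(REAL(slice), h, w, REAL(params), depth, cycle,
                   stack.data(), REAL(prob));
  prob.attr("dim") = IntegerVector::create(h, w, 2);
  List out = List::create(_["prob"] = prob);
  if (keep_stack) {
    NumericVector st(stack.begin(), stack.end());
    st.attr("dim") = IntegerVector::create(h, w, depth + 1);
    out["stack"] = st;
  }
  return out;
}

// Per-pixel mean two-class cross-entropy and its gradient wrt all parameters.
static double msd_loss_grad_impl(const double* x, const double* y, int h, int w,
                                 const double* par, int d, int cycle,
                                 double* grad /* zeroed, length total */) {
  const Layout L(d);
  const int npx = h * w;
  std::vector<double> stack((size_t)(d + 1) * npx);
  std::vector<double> prob(2 * (size_t)npx);
  msd_forward_impl(x, h, w, par, d, cycle, stack.data(), prob.data());

  const double eps = 1e-12;
  double loss = 0.0;
  // dlogit_c = (p_c - y_c) / npx  (softmax + cross-entropy)
  std::vector<double> dl0(npx), dl1(npx);
  for (int p = 0; p < npx; ++p) {
    const double t = y[p]; // 1 = bone
    const double pb = prob[npx + p], pg = prob[p];
    loss -= t * std::log(pb + eps) + (1.0 - t) * std::log(pg + eps);
    dl0[p] = (pg - (1.0 - t)) / npx;
    dl1[p] = (pb - t) / npx;
  }
  loss /= npx;

  // output layer gradients and dz seeds
  std::vector<double> dz((size_t)(d + 1) * npx, 0.0);
  const double* w0 = par + L.W;
  const double* w1 = par + L.W + (d + 1);
  double gb0 = 0.0, gb1 = 0.0;
  for (int p = 0; p < npx; ++p) { gb0 += dl0[p]; gb1 += dl1[p]; }
  grad[L.B] += gb0;
  grad[L.B + 1] += gb1;
  for (int i = 0; i <= d; ++i) {
    const double* zi = stack.data() + (size_t)i * npx;
    double* dzi = dz.data() + (size_t)i * npx;
    double gw0 = 0.0, gw1 = 0.0;
    for (int p = 0; p < npx; ++p) {
      gw0 += dl0[p] * zi[p];
      gw1 += dl1[p] * zi[p];
      dzi[p] = w0[i] * dl0[p] + w1[i] * dl1[p];
    }
    grad[L.W + i] += gw0;
    grad[L.W + (d + 1) + i] += gw1;
  }

  // backprop through the dense hidden layers
  std::vector<double> g(npx);
  for (int i = d; i >= 1; --i) {
    const int s = dilation_at(i, cycle);
    const double* zi = stack.data() + (size_t)i * npx;
    const double* dzi = dz.data() + (size_t)i * npx;
    double gbi = 0.0;
    for (int p = 0; p < npx; ++p) {
      g[p] = zi[p] > 0.0 ? dzi[p] : 0.0; // ReLU mask
      gbi += g[p];
    }
    grad[L.K + (i - 1)] += gbi;
    for (int j = 0; j < i; ++j) {
      const double* zj = stack.data() + (size_t)j * npx;
      dilated_conv_kernel_grad(g.data(), zj, h, w, s,
                               grad + kernel_offset(i, j));
      dilated_conv_adjoint(g.data(), h, w, par + kernel_offset(i, j), s,
                           dz.data() + (size_t)j * npx);
    }
  }
  return loss;
}

// [[Rcpp::export]]
List cpp_msd_loss_grad(NumericMatrix slice, NumericMatrix mask,
                       NumericVector params, int depth, int cycle) {
  const Layout L(depth);
  NumericVector grad(L.total);
  const double loss = msd_loss_grad_impl(REAL(slice), REAL(mask),
                                         slice.nrow(), slice.ncol(),
                                         REAL(params), depth, cycle,
                                         REAL(grad));
  return List::create(_["loss"] = loss, _["grad"] = grad);
}

// Batch-size-1 Adam over a pre-shuffled visiting order (0-based slice indices).
// [[Rcpp::export]]
List cpp_msd_train(NumericVector slices, NumericVector masks,
                   NumericVector params, int depth, int cycle,
                   IntegerVector order, double lr, double beta1, double beta2,
                   double eps) {
  IntegerVector dim = slices.attr("dim");
  const int h = dim[0], w = dim[1];
  const int npx = h * w;
  const Layout L(depth);
  NumericVector par = clone(params);
  const int steps = order.size();
  NumericVector losses(steps);
  std::vector<double> grad(L.total), m(L.total, 0.0), v(L.total, 0.0);
  double b1t = 1.0, b2t = 1.0;
  for (int t = 0; t < steps; ++t) {
    const int k = order[t];
    std::fill(grad.begin(), grad.end(), 0.0);
    losses[t] = msd_loss_grad_impl(REAL(slices) + (size_t)k * npx,
                                   REAL(masks) + (size_t)k * npx, h, w,
                                   REAL(par), depth, cycle, grad.data());
    b1t *= beta1;
    b2t *= beta2;
    const double corr = std::sqrt(1.0 - b2t) / (1.0 - b1t);
    for (int p = 0; p < L.total; ++p) {
      m[p] = beta1 * m[p] + (1.0 - beta1) * grad[p];
      v[p] = beta2 * v[p] + (1.0 - beta2) * grad[p] * grad[p];
      par[p] -= lr * corr * m[p] / (std::sqrt(v[p]) + eps);
    }
    if (t % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = par, _["losses"] = losses);
}

// Bone-probability maps for every axial slice of a volume (slice = 3rd index).
// [[Rcpp::export]]
NumericVector cpp_msd_predict(NumericVector volume, NumericVector params,
                              int depth, int cycle) {
  IntegerVector dim = volume.attr("dim");
  const int h = dim[0], w = dim[1], n = dim[2];
  const int npx = h * w;
  NumericVector out(volume.size());
  std::vector<double> stack((size_t)(depth + 1) * npx);
  std::vector<double> prob(2 * (size_t)npx);
  for (int k = 0; k < n; ++k) {
    msd_forward_impl(REAL(volume) + (size_t)k * npx, h, w, REAL(params),
                     depth, cycle, stack.data(), prob.data());
    std::copy(prob.begin() + npx, prob.end(), REAL(out) + (size_t)k * npx);
    Rcpp::checkUserInterrupt();
  }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Parallel-beam projection geometry. Image pixel (r, c) sits at
// (x, y) = (c - cx, r - cy) in pixel units, cx = (w-1)/2, cy = (h-1)/2.
// Detector bin k has signed offset t_k = k - (nbins-1)/2 pixels.
// ---------------------------------------------------------------------------

static inline double bilinear(const double* img, int h, int w, double x,
                              double y) {
  // x = column coordinate, y = row coordinate; zero outside the grid
  if (x < 0.0 || y < 0.0 || x > w - 1.0 || y > h - 1.0) return 0.0;
  int c0 = (int)std::floor(x), r0 = (int)std::floor(y);
  if (c0 >= w - 1) c0 = w - 2;
  if (r0 >= h - 1) r0 = h - 2;
  if (w == 1) c0 = 0;
  if (h == 1) r0 = 0;
  const double fx = x - c0, fy = y - r0;
  const int c1 = (w == 1) ? c0 : c0 + 1, r1 = (h == 1) ? r0 : r0 + 1;
  return (1 - fx) * ((1 - fy) * img[r0 + c0 * h] + fy * img[r1 + c0 * h]) +
         fx * ((1 - fy) * img[r0 + c1 * h] + fy * img[r1 + c1 * h]);
}

// Each detector bin averages `nsub` sub-rays across its unit width
// (detector aperture integration); samples along each ray are `step` px
// apart with bilinear interpolation.
// [[Rcpp::export]]
NumericMatrix cpp_radon(NumericMatrix map, NumericVector angles, int nbins,
                        double spacing, double step, int nsub) {
  const int h = map.nrow(), w = map.ncol();
  const int nang = angles.size();
  const double cx = (w - 1) / 2.0, cy = (h - 1) / 2.0;
  const double tc = (nbins - 1) / 2.0;
  const double L = std::sqrt((double)h * h + (double)w * w) + 2.0;
  const int nu = (int)std::ceil(L / step);
  NumericMatrix sino(nang, nbins);
  const double* img = REAL(map);
  for (int a = 0; a < nang; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int k = 0; k < nbins; ++k) {
      double acc = 0.0;
      for (int isub = 0; isub < nsub; ++isub) {
        const double t = k - tc + (isub + 0.5) / nsub - 0.5;
        for (int iu = 0; iu < nu; ++iu) {
          const double u = -L / 2.0 + (iu + 0.5) * step;
          const double x = cx + t * ct - u * st;
          const double y = cy + t * st + u * ct;
          acc += bilinear(img, h, w, x, y);
        }
      }
      sino(a, k) = acc * step * spacing / nsub; // line integral in mm units
    }
    Rcpp::checkUserInterrupt();
  }
  return sino;
}

// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix filtered, NumericVector angles,
                              int h, int w) {
  const int nang = angles.size(), nbins = filtered.ncol();
  const double cx = (w - 1) / 2.0, cy = (h - 1) / 2.0;
  const double tc = (nbins - 1) / 2.0;
  NumericMatrix out(h, w);
  for (int a = 0; a < nang; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int c = 0; c < w; ++c) {
      const double x = c - cx;
      for (int r = 0; r < h; ++r) {
        const double y = r - cy;
        const double t = x * ct + y * st + tc;
        if (t < 0.0 || t > nbins - 1.0) continue;
        int k0 = (int)std::floor(t);
        if (k0 >= nbins - 1) k0 = nbins - 2;
        const double f = t - k0;
        out(r, c) += (1.0 - f) * filtered(a, k0) + f * filtered(a, k0 + 1);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  const double scale = M_PI / nang;
  for (int i = 0; i < h * w; ++i) REAL(out)[i] *= scale;
  return out;
}

// ---------------------------------------------------------------------------
// Point-to-mesh signed distances (Ericson's closest-point-on-triangle).
// ---------------------------------------------------------------------------

static void closest_on_triangle(const double* p, const double* a,
                                const double* b, const double* c,
                                double* out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  const double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  const double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { std::copy(a, a + 3, out); return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  const double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  const double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) { std::copy(b, b + 3, out); return; }
  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    const double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  const double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  const double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) { std::copy(c, c + 3, out); return; }
  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    const double wg = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + wg * ac[i];
    return;
  }
  const double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    const double wg = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + wg * (c[i] - b[i]);
    return;
  }
  const double denom = 1.0 / (va + vb + vc);
  const double v = vb * denom, wg = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * wg;
}

// points: n x 3; verts: m x 3; tris: t x 3 (0-based); normals: t x 3 (unit,
// outward). Returns signed distance to the nearest point on the mesh, the
// sign taken from the nearest triangle's outward normal (>= 0 -> outside).
// [[Rcpp::export]]
NumericVector cpp_point_mesh_signed(NumericMatrix points, NumericMatrix verts,
                                    IntegerMatrix tris, NumericMatrix normals) {
  const int np = points.nrow(), nt = tris.nrow();
  NumericVector out(np);
  for (int ip = 0; ip < np; ++ip) {
    double p[3] = { points(ip, 0), points(ip, 1), points(ip, 2) };
    double best = R_PosInf, bestpt[3] = { 0, 0, 0 };
    int besttri = -1;
    double q[3];
    for (int it = 0; it < nt; ++it) {
      double A[3], B[3], C[3];
      for (int i = 0; i < 3; ++i) {
        A[i] = verts(tris(it, 0), i);
        B[i] = verts(tris(it, 1), i);
        C[i] = verts(tris(it, 2), i);
      }
      closest_on_triangle(p, A, B, C, q);
      const double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        besttri = it;
        std::copy(q, q + 3, bestpt);
      }
    }
    const double d = std::sqrt(best);
    double dotn = 0.0;
    for (int i = 0; i < 3; ++i)
      dotn += (p[i] - bestpt[i]) * normals(besttri, i);
    out[ip] = dotn >= 0.0 ? d : -d;
    if (ip % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
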