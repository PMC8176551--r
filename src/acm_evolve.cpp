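#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fast active-contour inner loop: {region means -> data-force step ->
// Gaussian smoothing + binarization [-> bright-phase orientation]}.
// Mirrors the R-level operations (region_means, evolve_step,
// smooth_binarize) composed by the package; hot loop lives here because
// per-pixel work on every iteration dominates the tracker's runtime.

static inline double heps(double z, double eps) {
  return 0.5 * (1.0 + (2.0 / M_PI) * std::atan(z / eps));
}

static inline double deps(double z, double eps) {
  return (eps / M_PI) / (eps * eps + z * z);
}

// separable Gaussian with replicate padding, taps exp(-k^2/2s^2),
// radius ceil(3s), normalized
static void gauss_smooth(const std::vector<double>& in,
                         std::vector<double>& tmp,
                         std::vector<double>& out,
                         int H, int W, double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int j = -r; j <= r; ++j) {
    k[j + r] = std::exp(-(double)(j * j) / (2.0 * sigma * sigma));
    s += k[j + r];
  }
  for (int j = 0; j <= 2 * r; ++j) k[j] /= s;
  // along rows (y direction), column-major layout: in[i + H*j]
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int ii = i + t;
        if (ii < 0) ii = 0;
        if (ii >= H) ii = H - 1;
        acc += k[t + r] * in[ii + (size_t)H * j];
      }
      tmp[i + (size_t)H * j] = acc;
    }
  }
  // along columns (x direction)
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int jj = j + t;
        if (jj < 0) jj = 0;
        if (jj >= W) jj = W - 1;
        acc += k[t + r] * tmp[i + (size_t)H * jj];
      }
      out[i + (size_t)H * j] = acc;
    }
  }
}

// [[Rcpp::export(name = ".acm_evolve_cpp")]]
List acm_evolve_cpp(NumericMatrix field, NumericMatrix phi0,
                    double lambda1, double lambda2, double mu, double nu,
                    double epsilon, double dt, double sigma, double level,
                    int iters, int stable_iters, bool orient_bright) {
  int H = field.nrow(), W = field.ncol();
  size_t n = (size_t)H * W;
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> f(field.begin(), field.end());
  std::vector<double> tmp(n), sm(n), force(n);
  std::vector<char> mask(n), prev_mask(n);
  std::vector<double> energy;
  energy.reserve(iters > 0 ? iters : 0);
  bool degenerate;
  int stable = 0, it = 0;
  double fsum = 0.0;
  for (size_t p = 0; p < n; ++p) fsum += f[p];
  double fmean = fsum / (double)n;
  for (size_t p = 0; p < n; ++p) prev_mask[p] = phi[p] > 0;

  while (it < iters) {
    ++it;
    // region means under the regularized Heaviside
    double sh = 0.0, sfh = 0.0;
    for (size_t p = 0; p < n; ++p) {
      double h = heps(phi[p], epsilon);
      sh += h;
      sfh += f[p] * h;
    }
    double so = (double)n - sh, sfo = fsum - sfh;
    double m1 = (sh > 1e-8) ? sfh / sh : fmean;
    double m2 = (so > 1e-8) ? sfo / so : fmean;
    // data force, normalized by its maximum magnitude
    double ma = 0.0;
    for (size_t p = 0; p < n; ++p) {
      double d1 = f[p] - m1, d2 = f[p] - m2;
      double fo = deps(phi[p], epsilon) * (-lambda1 * d1 * d1 + lambda2 * d2 * d2);
      force[p] = fo;
      double a = std::fabs(fo);
      if (a > ma) ma = a;
    }
    // floor the normalizer: rounding-noise forces on a numerically uniform
    // field must not be amplified to unit strength; a zero-force field is
    // stationary, so the iteration (including regularization) is a no-op
    if (ma <= 1e-12) {
      --it;
      break;
    }
    for (size_t p = 0; p < n; ++p) phi[p] += dt * force[p] / ma;
    // regularization on the phase labels: binarize the evolved field
    // first so the Gaussian acts as an equal-vote majority filter
    // (amplitude-weighted votes would dilate the stronger-force phase)
    for (size_t p = 0; p < n; ++p) phi[p] = (phi[p] >= 0.0) ? level : -level;
    gauss_smooth(phi, tmp, sm, H, W, sigma);
    for (size_t p = 0; p < n; ++p) phi[p] = (sm[p] >= 0.0) ? level : -level;
    // keep the bright phase inside
    size_t n_in = 0;
    for (size_t p = 0; p < n; ++p) if (phi[p] > 0) ++n_in;
    if (orient_bright && n_in > 0 && n_in < n) {
      double si = 0.0;
      for (size_t p = 0; p < n; ++p) if (phi[p] > 0) si += f[p];
      double mi = si / (double)n_in;
      double mo = (fsum - si) / (double)(n - n_in);
      if (mi < mo) {
        for (size_t p = 0; p < n; ++p) phi[p] = -phi[p];
        n_in = n - n_in;
      }
    }
    // energy trace (descent monitor)
    double sh2 = 0.0, sfh2 = 0.0;
    for (size_t p = 0; p < n; ++p) {
      double h = heps(phi[p], epsilon);
      sh2 += h;
      sfh2 += f[p] * h;
    }
    double so2 = (double)n - sh2, sfo2 = fsum - sfh2;
    double e1 = (sh2 > 1e-8) ? sfh2 / sh2 : fmean;
    double e2 = (so2 > 1e-8) ? sfo2 / so2 : fmean;
    double en = 0.0;
    for (size_t p = 0; p < n; ++p) {
      double h = heps(phi[p], epsilon);
      double d1 = f[p] - e1, d2 = f[p] - e2;
      en += lambda1 * d1 * d1 * h + lambda2 * d2 * d2 * (1.0 - h);
    }
    if (mu > 0.0) {
      // mu * sum(dirac * |grad phi|), central differences, replicate pad
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          int ip = (i + 1 < H) ? i + 1 : H - 1, im = (i > 0) ? i - 1 : 0;
          int jp = (j + 1 < W) ? j + 1 : W - 1, jm = (j > 0) ? j - 1 : 0;
          double gy = (phi[ip + (size_t)H * j] - phi[im + (size_t)H * j]) / 2.0;
          double gx = (phi[i + (size_t)H * jp] - phi[i + (size_t)H * jm]) / 2.0;
          en += mu * deps(phi[i + (size_t)H * j], epsilon) *
            std::sqrt(gx * gx + gy * gy);
        }
      }
    }
    if (nu != 0.0) en += nu * sh2;
    energy.push_back(en);
    // convergence bookkeeping on the binary mask
    for (size_t p = 0; p < n; ++p) mask[p] = phi[p] > 0;
    if (n_in == 0 || n_in == n) break;
    bool same = true;
    for (size_t p = 0; p < n; ++p)
      if (mask[p] != prev_mask[p]) { same = false; break; }
    stable = same ? stable + 1 : 0;
    prev_mask = mask;
    if (stable >= stable_iters) break;
  }
  size_t n_fin = 0;
  for (size_t p = 0; p < n; ++p) if (phi[p] > 0) ++n_fin;
  degenerate = (n_fin == 0 || n_fin == n);
  NumericMatrix phi_out(H, W);
  std::copy(phi.begin(), phi.end(), phi_out.begin());
  return List::create(_["phi"] = phi_out,
                      _["iterations"] = it,
                      _["energy"] = NumericVector(energy.begin(), energy.end()),
                      _["degenerate"] = degenerate);
}
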