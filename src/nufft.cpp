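#include <Rcpp.h>
#include <complex>
#include <cmath>
using namespace Rcpp;

typedef std::complex<double> cplx;

// Linear interpolation into a kernel lookup table sampled at u = 0 .. W/2
// (nt points, spacing du). Out-of-range |u| > W/2 returns 0.
static inline double kb_lookup(double u, const double* tab, int nt, double du) {
  u = std::fabs(u);
  double pos = u / du;
  int i0 = (int)pos;
  if (i0 >= nt - 1) return 0.0;
  double f = pos - i0;
  return tab[i0] * (1.0 - f) + tab[i0 + 1] * f;
}

static inline int wrap(int g, int G) {
  int r = g % G;
  return r < 0 ? r + G : r;
}

// Interpolate oversampled-grid spectrum F (G1 x G2 x G3, column-major) at
// off-grid coordinates (K x 3, in oversampled grid units).
// [[Rcpp::export]]
ComplexVector cpp_kb_interp(ComplexVector F, IntegerVector Gdim,
                            NumericMatrix coords, double W,
                            NumericVector table) {
  int G1 = Gdim[0], G2 = Gdim[1], G3 = Gdim[2];
  int K = coords.nrow();
  int nt = table.size();
  double du = (W / 2.0) / (nt - 1);
  const double* tab = table.begin();
  const cplx* Fp = reinterpret_cast<const cplx*>(F.begin());
  ComplexVector out(K);
  cplx* op = reinterpret_cast<cplx*>(out.begin());
  double half = W / 2.0;
  for (int k = 0; k < K; ++k) {
    double kx = coords(k, 0), ky = coords(k, 1), kz = coords(k, 2);
    int x0 = (int)std::ceil(kx - half), x1 = (int)std::floor(kx + half);
    int y0 = (int)std::ceil(ky - half), y1 = (int)std::floor(ky + half);
    int z0 = (int)std::ceil(kz - half), z1 = (int)std::floor(kz + half);
    cplx acc(0.0, 0.0);
    for (int gz = z0; gz <= z1; ++gz) {
      double wz = kb_lookup(kz - gz, tab, nt, du);
      if (wz == 0.0) continue;
      int iz = wrap(gz, G3);
      for (int gy = y0; gy <= y1; ++gy) {
        double wy = kb_lookup(ky - gy, tab, nt, du) * wz;
        if (wy == 0.0) continue;
        int iy = wrap(gy, G2);
        size_t base = (size_t)iz * G1 * G2 + (size_t)iy * G1;
        for (int gx = x0; gx <= x1; ++gx) {
          double wx = kb_lookup(kx - gx, tab, nt, du);
          if (wx == 0.0) continue;
          acc += wx * wy * Fp[base + wrap(gx, G1)];
        }
      }
    }
    op[k] = acc;
  }
  return out;
}

// Adjoint of cpp_kb_interp: spread sample values y onto the oversampled grid.
// [[Rcpp::export]]
ComplexVector cpp_kb_spread(ComplexVector y, IntegerVector Gdim,
                            NumericMatrix coords, double W,
                            NumericVector table) {
  int G1 = Gdim[0], G2 = Gdim[1], G3 = Gdim[2];
  int K = coords.nrow();
  int nt = table.size();
  double du = (W / 2.0) / (nt - 1);
  const double* tab = table.begin();
  const cplx* yp = reinterpret_cast<const cplx*>(y.begin());
  ComplexVector out((size_t)G1 * G2 * G3);
  cplx* op = reinterpret_cast<cplx*>(out.begin());
  std::fill(op, op + (size_t)G1 * G2 * G3, cplx(0.0, 0.0));
  double half = W / 2.0;
  for (int k = 0; k < K; ++k) {
    double kx = coords(k, 0), ky = coords(k, 1), kz = coords(k, 2);
    int x0 = (int)std::ceil(kx - half), x1 = (int)std::floor(kx + half);
    int y0 = (int)std::ceil(ky - half), y1 = (int)std::floor(ky + half);
    int z0 = (int)std::ceil(kz - half), z1 = (int)std::floor(kz + half);
    cplx val = yp[k];
    for (int gz = z0; gz <= z1; ++gz) {
      double wz = kb_lookup(kz - gz, tab, nt, du);
      if (wz == 0.0) continue;
      int iz = wrap(gz, G3);
      for (int gy = y0; gy <= y1; ++gy) {
        double wy = kb_lookup(ky - gy, tab, nt, du) * wz;
        if (wy == 0.0) continue;
        int iy = wrap(gy, G2);
        size_t base = (size_t)iz * G1 * G2 + (size_t)iy * G1;
        for (int gx = x0; gx <= x1; ++gx) {
          double wx = kb_lookup(kx - gx, tab, nt, du);
          if (wx == 0.0) continue;
          op[base + wrap(gx, G1)] += wx * wy * val;
        }
      }
    }
  }
  return out;
}

// Derivative of the interpolation step with respect to the (oversampled-grid)
// coordinates, using a lookup table of the kernel derivative. This is the
// "interpolation-kernel autodiff" gradient that frameworks produce when
// differentiating through gridding; kept for comparison against the analytic
// Jacobian route.
// [[Rcpp::export]]
ComplexMatrix cpp_kb_interp_dcoord(ComplexVector F, IntegerVector Gdim,
                                   NumericMatrix coords, double W,
                                   NumericVector table, NumericVector dtable) {
  int G1 = Gdim[0], G2 = Gdim[1], G3 = Gdim[2];
  int K = coords.nrow();
  int nt = table.size();
  double du = (W / 2.0) / (nt - 1);
  const double* tab = table.begin();
  const double* dtab = dtable.begin();
  const cplx* Fp = reinterpret_cast<const cplx*>(F.begin());
  ComplexMatrix out(K, 3);
  cplx* op = reinterpret_cast<cplx*>(out.begin());
  double half = W / 2.0;
  for (int k = 0; k < K; ++k) {
    double kc[3] = {coords(k, 0), coords(k, 1), coords(k, 2)};
    cplx acc[3] = {cplx(0, 0), cplx(0, 0), cplx(0, 0)};
    int x0 = (int)std::ceil(kc[0] - half), x1 = (int)std::floor(kc[0] + half);
    int y0 = (int)std::ceil(kc[1] - half), y1 = (int)std::floor(kc[1] + half);
    int z0 = (int)std::ceil(kc[2] - half), z1 = (int)std::floor(kc[2] + half);
    for (int gz = z0; gz <= z1; ++gz) {
      double uz = kc[2] - gz;
      double wz = kb_lookup(uz, tab, nt, du);
      double dz = kb_lookup(uz, dtab, nt, du) * (uz < 0 ? -1.0 : 1.0);
      int iz = wrap(gz, G3);
      for (int gy = y0; gy <= y1; ++gy) {
        double uy = kc[1] - gy;
        double wy = kb_lookup(uy, tab, nt, du);
        double dy = kb_lookup(uy, dtab, nt, du) * (uy < 0 ? -1.0 : 1.0);
        int iy = wrap(gy, G2);
        size_t base = (size_t)iz * G1 * G2 + (size_t)iy * G1;
        for (int gx = x0; gx <= x1; ++gx) {
          double ux = kc[0] - gx;
          double wx = kb_lookup(ux, tab, nt, du);
          double dx = kb_lookup(ux, dtab, nt, du) * (ux < 0 ? -1.0 : 1.0);
          cplx Fv = Fp[base + wrap(gx, G1)];
          acc[0] += dx * wy * wz * Fv;
          acc[1] += wx * dy * wz * Fv;
          acc[2] += wx * wy * dz * Fv;
        }
      }
    }
    op[k] = acc[0];
    op[k + K] = acc[1];
    op[k + 2 * (size_t)K] = acc[2];
  }
  return out;
}

// Exact (slow) type-2 discrete Fourier transform on an N1 x N2 x N3 image with
// voxel coordinates centered at zero: y[k] = sum_x m(x) exp(-2 pi i k.x / N).
// Used as the float64 oracle / exact mode on small problems.
// [[Rcpp::export]]
ComplexVector cpp_dft3_forward(ComplexVector m, IntegerVector Ndim,
                               NumericMatrix coords) {
  int N1 = Ndim[0], N2 = Ndim[1], N3 = Ndim[2];
  int K = coords.nrow();
  const cplx* mp = reinterpret_cast<const cplx*>(m.begin());
  ComplexVector out(K);
  cplx* op = reinterpret_cast<cplx*>(out.begin());
  double c1 = -2.0 * M_PI / N1, c2 = -2.0 * M_PI / N2, c3 = -2.0 * M_PI / N3;
  for (int k = 0; k < K; ++k) {
    double kx = coords(k, 0), ky = coords(k, 1), kz = coords(k, 2);
    cplx acc(0, 0);
    size_t idx = 0;
    for (int z = 0; z < N3; ++z) {
      double pz = c3 * kz * (z - N3 / 2);
      for (int y = 0; y < N2; ++y) {
        double py = c2 * ky * (y - N2 / 2) + pz;
        for (int x = 0; x < N1; ++x, ++idx) {
          double ph = c1 * kx * (x - N1 / 2) + py;
          acc += mp[idx] * cplx(std::cos(ph), std::sin(ph));
        }
      }
    }
    op[k] = acc;
  }
  return out;
}

// Exact adjoint of cpp_dft3_forward.
// [[Rcpp::export]]
ComplexVector cpp_dft3_adjoint(ComplexVector y, IntegerVector Ndim,
                               NumericMatrix coords) {
  int N1 = Ndim[0], N2 = Ndim[1], N3 = Ndim[2];
  int K = coords.nrow();
  const cplx* yp = reinterpret_cast<const cplx*>(y.begin());
  ComplexVector out((size_t)N1 * N2 * N3);
  cplx* op = reinterpret_cast<cplx*>(out.begin());
  std::fill(op, op + (size_t)N1 * N2 * N3, cplx(0, 0));
  double c1 = 2.0 * M_PI / N1, c2 = 2.0 * M_PI / N2, c3 = 2.0 * M_PI / N3;
  for (int k = 0; k < K; ++k) {
    double kx = coords(k, 0), ky = coords(k, 1), kz = coords(k, 2);
    cplx val = yp[k];
    size_t idx = 0;
    for (int z = 0; z < N3; ++z) {
      double pz = c3 * kz * (z - N3 / 2);
      for (int y2 = 0; y2 < N2; ++y2) {
        double py = c2 * ky * (y2 - N2 / 2) + pz;
        for (int x = 0; x < N1; ++x, ++idx) {
          double ph = c1 * kx * (x - N1 / 2) + py;
          op[idx] += val * cplx(std::cos(ph), std::sin(ph));
        }
      }
    }
  }
  return out;
}

// Greedy variable-density dart throwing. Candidates (K x 2) are visited in
// order; a candidate is kept when its distance to every kept point p exceeds
// min(rho(candidate), rho(p)) with rho(rad) = max(1, 1 + slope*(rad - rc)).
// Returns indices (1-based) of accepted candidates.
// [[Rcpp::export]]
IntegerVector cpp_poisson_disc(NumericMatrix cand, double N, double rc,
                               double slope) {
  int K = cand.nrow();
  double half = N / 2.0;
  // background grid with cell size 1 (the minimum spacing)
  int nc = (int)std::ceil(N) + 2;
  std::vector<std::vector<int>> cells((size_t)nc * nc);
  std::vector<double> px, py, prho;
  std::vector<int> keep;
  for (int i = 0; i < K; ++i) {
    double x = cand(i, 0), y = cand(i, 1);
    double rad = std::sqrt(x * x + y * y);
    double rho = 1.0 + slope * (rad - rc);
    if (rho < 1.0) rho = 1.0;
    int cx = (int)(x + half), cy = (int)(y + half);
    int reach = (int)std::ceil(rho) + 1;
    bool ok = true;
    for (int gy = std::max(0, cy - reach); ok && gy <= std::min(nc - 1, cy + reach); ++gy)
      for (int gx = std::max(0, cx - reach); ok && gx <= std::min(nc - 1, cx + reach); ++gx) {
        const std::vector<int>& cell = cells[(size_t)gy * nc + gx];
        for (size_t j = 0; j < cell.size(); ++j) {
          int p = cell[j];
          double dx = x - px[p], dy = y - py[p];
          double lim = std::min(rho, prho[p]);
          if (dx * dx + dy * dy < lim * lim) { ok = false; break; }
        }
      }
    if (ok) {
      px.push_back(x); py.push_back(y); prho.push_back(rho);
      cells[(size_t)cy * nc + cx].push_back((int)px.size() - 1);
      keep.push_back(i + 1);
    }
  }
  return wrap(keep);
}

// Precompute a separable interpolation plan for fixed coordinates: per-axis
// wrapped grid indices (0-based) and kernel weights, W+1 taps per axis
// (trailing taps zero-weighted where the support covers only W integers).
// [[Rcpp::export]]
List cpp_kb_plan(NumericMatrix coords, IntegerVector Gdim, double W,
                 NumericVector table) {
  int K = coords.nrow();
  int nt = table.size();
  double du = (W / 2.0) / (nt - 1);
  const double* tab = table.begin();
  int T = (int)W + 1;
  IntegerMatrix idx(K, 3 * T);
  NumericMatrix wgt(K, 3 * T);
  double half = W / 2.0;
  for (int k = 0; k < K; ++k)
    for (int d = 0; d < 3; ++d) {
      double c = coords(k, d);
      int G = Gdim[d];
      int g0 = (int)std::ceil(c - half);
      for (int t = 0; t < T; ++t) {
        int g = g0 + t;
        double u = c - g;
        double w = (std::fabs(u) <= half) ? kb_lookup(u, tab, nt, du) : 0.0;
        idx(k, d * T + t) = wrap(g, G);
        wgt(k, d * T + t) = w;
      }
    }
  return List::create(Named("idx") = idx, Named("wgt") = wgt,
                      Named("taps") = T);
}

// [[Rcpp::export]]
ComplexVector cpp_kb_interp_plan(ComplexVector F, IntegerVector Gdim,
                                 IntegerMatrix idx, NumericMatrix wgt,
                                 int T) {
  int G1 = Gdim[0], G2 = Gdim[1];
  int K = idx.nrow();
  const cplx* Fp = reinterpret_cast<const cplx*>(F.begin());
  ComplexVector out(K);
  cplx* op = reinterpret_cast<cplx*>(out.begin());
  for (int k = 0; k < K; ++k) {
    cplx acc(0.0, 0.0);
    for (int tz = 0; tz < T; ++tz) {
      double wz = wgt(k, 2 * T + tz);
      if (wz == 0.0) continue;
      size_t bz = (size_t)idx(k, 2 * T + tz) * G1 * G2;
      for (int ty = 0; ty < T; ++ty) {
        double wyz = wgt(k, T + ty) * wz;
        if (wyz == 0.0) continue;
        size_t byz = bz + (size_t)idx(k, T + ty) * G1;
        for (int tx = 0; tx < T; ++tx) {
          double w = wgt(k, tx) * wyz;
          if (w == 0.0) continue;
          acc += w * Fp[byz + idx(k, tx)];
        }
      }
    }
    op[k] = acc;
  }
  return out;
}

// [[Rcpp::export]]
ComplexVector cpp_kb_spread_plan(ComplexVector y, IntegerVector Gdim,
                                 IntegerMatrix idx, NumericMatrix wgt,
                                 int T) {
  int G1 = Gdim[0], G2 = Gdim[1], G3 = Gdim[2];
  int K = idx.nrow();
  const cplx* yp = reinterpret_cast<const cplx*>(y.begin());
  ComplexVector out((size_t)G1 * G2 * G3);
  cplx* op = reinterpret_cast<cplx*>(out.begin());
  std::fill(op, op + (size_t)G1 * G2 * G3, cplx(0.0, 0.0));
  for (int k = 0; k < K; ++k) {
    cplx val = yp[k];
    for (int tz = 0; tz < T; ++tz) {
      double wz = wgt(k, 2 * T + tz);
      if (wz == 0.0) continue;
      size_t bz = (size_t)idx(k, 2 * T + tz) * G1 * G2;
      for (int ty = 0; ty < T; ++ty) {
        double wyz = wgt(k, T + ty) * wz;
        if (wyz == 0.0) continue;
        size_t byz = bz + (size_t)idx(k, T + ty) * G1;
        for (int tx = 0; tx < T; ++tx) {
          double w = wgt(k, tx) * wyz;
          if (w == 0.0) continue;
          op[byz + idx(k, tx)] += w * val;
        }
      }
    }
  }
  return out;
}
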