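#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Zero-pad one channel of (nx, ny, nz) into (nx+2h, ny+2h, nz+2h).
static void pad_channel(const double* in, double* pad, int nx, int ny, int nz,
                        int h) {
  int px = nx + 2 * h, py = ny + 2 * h, pz = nz + 2 * h;
  std::fill(pad, pad + (size_t)px * py * pz, 0.0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const double* src = in + (size_t)z * nx * ny + (size_t)y * nx;
      double* dst = pad + (size_t)(z + h) * px * py + (size_t)(y + h) * px + h;
      std::copy(src, src + nx, dst);
    }
}

// 3D multi-channel cross-correlation ("convolution" in the CNN sense) with
// zero 'same' padding. input: (nx, ny, nz, cin), kernel: (kw, kw, kw, cin,
// cout), column-major; kernel offsets run -h..h with h = (kw-1)/2.
// out[x,y,z,co] = sum_{ci,dx,dy,dz} in[x+dx, y+dy, z+dz, ci] * k[dx,dy,dz,ci,co]
// [[Rcpp::export]]
NumericVector cpp_conv3d(NumericVector input, IntegerVector dims,
                         NumericVector kern, IntegerVector kdims) {
  int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  int kw = kdims[0], cout = kdims[4];
  int h = (kw - 1) / 2;
  int kk = kw * kw * kw;
  size_t vox = (size_t)nx * ny * nz;
  int px = nx + 2 * h, py = ny + 2 * h;
  size_t pvox = (size_t)px * py * (nz + 2 * h);
  std::vector<double> pad(pvox * cin);
  for (int ci = 0; ci < cin; ++ci)
    pad_channel(input.begin() + (size_t)ci * vox, pad.data() + pvox * ci,
                nx, ny, nz, h);
  // tap offsets into the padded volume, relative to the padded position of
  // the output voxel's (x-h, y-h, z-h) corner
  std::vector<long> off(kk);
  {
    int j = 0;
    for (int dz = 0; dz < kw; ++dz)
      for (int dy = 0; dy < kw; ++dy)
        for (int dx = 0; dx < kw; ++dx, ++j)
          off[j] = (long)dz * px * py + (long)dy * px + dx;
  }
  NumericVector out(vox * cout);
  double* op = out.begin();
  const double* kp = kern.begin();
  std::vector<double> kbuf((size_t)kk * cin);
  for (int co = 0; co < cout; ++co) {
    // kernel slice for this output channel: kbuf[ci*kk + j]
    for (int ci = 0; ci < cin; ++ci)
      for (int j = 0; j < kk; ++j)
        kbuf[(size_t)ci * kk + j] = kp[(size_t)j + kk * (ci + (size_t)cin * co)];
    double* oc = op + (size_t)co * vox;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        double* orow = oc + (size_t)z * nx * ny + (size_t)y * nx;
        for (int ci = 0; ci < cin; ++ci) {
          const double* base = pad.data() + pvox * ci +
            (size_t)z * px * py + (size_t)y * px;
          const double* kc = kbuf.data() + (size_t)ci * kk;
          for (int x = 0; x < nx; ++x) {
            const double* b = base + x;
            double acc = 0.0;
            for (int j = 0; j < kk; ++j) acc += kc[j] * b[off[j]];
            if (ci == 0) orow[x] = acc; else orow[x] += acc;
          }
        }
      }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return out;
}

// Weight gradient of cpp_conv3d:
// gk[dx,dy,dz,ci,co] = sum_{x,y,z} in[x+dx, y+dy, z+dz, ci] * gout[x,y,z,co]
// [[Rcpp::export]]
NumericVector cpp_conv3d_wgrad(NumericVector input, IntegerVector dims,
                               NumericVector gout, int kw, int cout) {
  int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  int h = (kw - 1) / 2;
  int kk = kw * kw * kw;
  size_t vox = (size_t)nx * ny * nz;
  int px = nx + 2 * h, py = ny + 2 * h;
  size_t pvox = (size_t)px * py * (nz + 2 * h);
  std::vector<double> pad(pvox * cin);
  for (int ci = 0; ci < cin; ++ci)
    pad_channel(input.begin() + (size_t)ci * vox, pad.data() + pvox * ci,
                nx, ny, nz, h);
  std::vector<long> off(kk);
  {
    int j = 0;
    for (int dz = 0; dz < kw; ++dz)
      for (int dy = 0; dy < kw; ++dy)
        for (int dx = 0; dx < kw; ++dx, ++j)
          off[j] = (long)dz * px * py + (long)dy * px + dx;
  }
  NumericVector gk((size_t)kk * cin * cout);
  double* gkp = gk.begin();
  const double* gp = gout.begin();
  std::vector<double> acc(kk);
  for (int co = 0; co < cout; ++co) {
    const double* gc = gp + (size_t)co * vox;
    for (int ci = 0; ci < cin; ++ci) {
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
          const double* grow = gc + (size_t)z * nx * ny + (size_t)y * nx;
          const double* base = pad.data() + pvox * ci +
            (size_t)z * px * py + (size_t)y * px;
          for (int x = 0; x < nx; ++x) {
            double g = grow[x];
            if (g == 0.0) continue;
            const double* b = base + x;
            for (int j = 0; j < kk; ++j) acc[j] += g * b[off[j]];
          }
        }
      for (int j = 0; j < kk; ++j)
        gkp[(size_t)j + kk * (ci + (size_t)cin * co)] = acc[j];
    }
  }
  gk.attr("dim") = IntegerVector::create(kw, kw, kw, cin, cout);
  return gk;
}
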