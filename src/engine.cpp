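// Compiled core of the 2DTM engine: real-space template projection and the
// FFT cross-correlation inner loop. Images and projections are stored
// column-major with the x (fast) axis first, i.e. element (x, y) of an
// nx-by-ny image sits at index y*nx + x, matching R matrices of dim (nx, ny).
#include <Rcpp.h>
#include <fftw3.h>
#include <complex>
#include <cmath>
#include <cstring>

using namespace Rcpp;

// ZYZ intrinsic rotation matrix (degrees): R = Rz(phi) * Ry(theta) * Rz(psi)
static void zyz_matrix(double phi, double theta, double psi, double R[3][3]) {
  const double d2r = M_PI / 180.0;
  double c1 = std::cos(phi * d2r),   s1 = std::sin(phi * d2r);
  double c2 = std::cos(theta * d2r), s2 = std::sin(theta * d2r);
  double c3 = std::cos(psi * d2r),   s3 = std::sin(psi * d2r);
  R[0][0] = c1 * c2 * c3 - s1 * s3;
  R[0][1] = -c1 * c2 * s3 - s1 * c3;
  R[0][2] = c1 * s2;
  R[1][0] = s1 * c2 * c3 + c1 * s3;
  R[1][1] = -s1 * c2 * s3 + c1 * c3;
  R[1][2] = s1 * s2;
  R[2][0] = -s2 * c3;
  R[2][1] = s2 * s3;
  R[2][2] = c2;
}

// Project a cubic volume along z after rotating it by the ZYZ angles.
// The rotated volume is W(r) = V(R^T (r - c) + c), c = floor(n/2) (0-based
// voxel coordinates); the projection is the sum of W over z. Trilinear
// interpolation; samples falling outside the grid contribute zero.
// [[Rcpp::export]]
NumericMatrix cpp_project_volume(NumericVector vol, int n,
                                 double phi, double theta, double psi) {
  double R[3][3];
  zyz_matrix(phi, theta, psi, R);
  double c = std::floor(n / 2.0);
  NumericMatrix out(n, n);
  const double* v = vol.begin();
  const int n2 = n * n;
  for (int z = 0; z < n; z++) {
    double dz = z - c;
    for (int y = 0; y < n; y++) {
      double dy = y - c;
      for (int x = 0; x < n; x++) {
        double dx = x - c;
        // R^T * (r - c) + c
        double sx = R[0][0] * dx + R[1][0] * dy + R[2][0] * dz + c;
        double sy = R[0][1] * dx + R[1][1] * dy + R[2][1] * dz + c;
        double sz = R[0][2] * dx + R[1][2] * dy + R[2][2] * dz + c;
        if (sx < 0 || sy < 0 || sz < 0 ||
            sx > n - 1 || sy > n - 1 || sz > n - 1) continue;
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
            z0 = (int)std::floor(sz);
        int x1 = x0 + 1 < n ? x0 + 1 : x0;
        int y1 = y0 + 1 < n ? y0 + 1 : y0;
        int z1 = z0 + 1 < n ? z0 + 1 : z0;
        double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        double c000 = v[x0 + n * y0 + n2 * z0], c100 = v[x1 + n * y0 + n2 * z0];
        double c010 = v[x0 + n * y1 + n2 * z0], c110 = v[x1 + n * y1 + n2 * z0];
        double c001 = v[x0 + n * y0 + n2 * z1], c101 = v[x1 + n * y0 + n2 * z1];
        double c011 = v[x0 + n * y1 + n2 * z1], c111 = v[x1 + n * y1 + n2 * z1];
        double c00 = c000 * (1 - fx) + c100 * fx;
        double c10 = c010 * (1 - fx) + c110 * fx;
        double c01 = c001 * (1 - fx) + c101 * fx;
        double c11 = c011 * (1 - fx) + c111 * fx;
        double c0 = c00 * (1 - fy) + c10 * fy;
        double c1 = c01 * (1 - fy) + c11 * fy;
        out(x, y) += c0 * (1 - fz) + c1 * fz;
      }
    }
  }
  return out;
}

// Exhaustive correlation of one whitened image against a stack of prepared
// (filtered, unit-norm) template projections. Circular correlation via FFT:
// corr_k(x, y) = sum_{u,v} image[(x+u-c) mod nx, (y+v-c) mod ny] * t_k[u, v],
// c = floor(nt/2), so a peak sits at the particle center. Two templates are
// processed per FFT pass by packing t_k + i*t_{k+1}: with real image I and
// real templates, ifft(F_I .* conj(fft(t_k + i t_{k+1}))) = corr_k - i corr_{k+1}.
// Updates the running MIP and argmax (1-based index into this stack, offset
// by index_offset) in place across calls via the accumulate arguments.
// [[Rcpp::export]]
List cpp_search_accumulate(NumericMatrix image, NumericVector templates,
                           int nt, int ntpl, int index_offset,
                           NumericMatrix mip, IntegerMatrix best) {
  int nx = image.nrow(), ny = image.ncol();
  size_t npx = (size_t)nx * ny;
  std::complex<double>* buf =
      (std::complex<double>*)fftw_malloc(sizeof(fftw_complex) * npx);
  std::complex<double>* fimg =
      (std::complex<double>*)fftw_malloc(sizeof(fftw_complex) * npx);
  // FFTW is row-major; our memory is column-major with x fastest, so pass
  // (ny, nx) and the transform matches the (x, y) layout untouched.
  fftw_plan fwd = fftw_plan_dft_2d(ny, nx,
      reinterpret_cast<fftw_complex*>(buf), reinterpret_cast<fftw_complex*>(buf),
      FFTW_FORWARD, FFTW_MEASURE);
  fftw_plan bwd = fftw_plan_dft_2d(ny, nx,
      reinterpret_cast<fftw_complex*>(buf), reinterpret_cast<fftw_complex*>(buf),
      FFTW_BACKWARD, FFTW_MEASURE);

  for (size_t i = 0; i < npx; i++) buf[i] = image[i];
  fftw_execute(fwd);
  std::memcpy(fimg, buf, sizeof(fftw_complex) * npx);

  int cshift = (int)std::floor(nt / 2.0);
  const double* tp = templates.begin();
  double scale = 1.0 / (double)npx;

  for (int k = 0; k < ntpl; k += 2) {
    bool pair = (k + 1 < ntpl);
    std::memset(buf, 0, sizeof(fftw_complex) * npx);
    const double* t1 = tp + (size_t)k * nt * nt;
    const double* t2 = pair ? tp + (size_t)(k + 1) * nt * nt : nullptr;
    for (int v = 0; v < nt; v++) {
      int b = (v - cshift + ny) % ny;
      for (int u = 0; u < nt; u++) {
        int a = (u - cshift + nx) % nx;
        double re = t1[u + nt * v];
        double im = pair ? t2[u + nt * v] : 0.0;
        buf[a + (size_t)nx * b] = std::complex<double>(re, im);
      }
    }
    fftw_execute(fwd);
    for (size_t i = 0; i < npx; i++) buf[i] = fimg[i] * std::conj(buf[i]);
    fftw_execute(bwd);
    for (size_t i = 0; i < npx; i++) {
      double c1 = buf[i].real() * scale;
      if (c1 > mip[i]) { mip[i] = c1; best[i] = index_offset + k + 1; }
      if (pair) {
        double c2 = -buf[i].imag() * scale;
        if (c2 > mip[i]) { mip[i] = c2; best[i] = index_offset + k + 2; }
      }
    }
    if (k % 64 == 0) Rcpp::checkUserInterrupt();
  }
  fftw_destroy_plan(fwd);
  fftw_destroy_plan(bwd);
  fftw_free(buf);
  fftw_free(fimg);
  return List::create(_["mip"] = mip, _["best"] = best);
}

// Single circular correlation of a prepared template centered at (x, y),
// identical arithmetic to one pixel of cpp_search_accumulate.
// [[Rcpp::export]]
double cpp_corr_at(NumericMatrix image, NumericMatrix templ, int x, int y) {
  int nx = image.nrow(), ny = image.ncol(), nt = templ.nrow();
  int c = (int)std::floor(nt / 2.0);
  double acc = 0.0;
  for (int v = 0; v < nt; v++) {
    int b = (y + v - c) % ny; if (b < 0) b += ny;
    for (int u = 0; u < nt; u++) {
      int a = (x + u - c) % nx; if (a < 0) a += nx;
      acc += image(a, b) * templ(u, v);
    }
  }
  return acc;
}
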