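// Seeded 3D gradient (Perlin) noise with octave composition.
// Gradients are drawn by a counter-based hash of (seed, lattice coords) so any
// sub-region is reproducible independently of evaluation order.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t hash_coords(uint64_t seed, int64_t ix, int64_t iy,
                                   int64_t iz, uint64_t ctr) {
  uint64_t h = splitmix64(seed ^ 0xA5A5A5A5DEADBEEFULL);
  h = splitmix64(h ^ (uint64_t)ix);
  h = splitmix64(h ^ (uint64_t)iy);
  h = splitmix64(h ^ (uint64_t)iz);
  h = splitmix64(h ^ ctr);
  return h;
}

// top 53 bits -> double in [0, 1)
static inline double u01(uint64_t h) {
  return (double)(h >> 11) * (1.0 / 9007199254740992.0);
}

// Uniform unit vector: rejection-sample the unit cube to the unit ball, then
// normalise. Counter-based so the draw is a pure function of (seed, coords).
static void lattice_gradient(uint64_t seed, int64_t ix, int64_t iy, int64_t iz,
                             double g[3]) {
  for (uint64_t attempt = 0;; ++attempt) {
    uint64_t h = hash_coords(seed, ix, iy, iz, attempt);
    double x = 2.0 * u01(splitmix64(h ^ 0x1ULL)) - 1.0;
    double y = 2.0 * u01(splitmix64(h ^ 0x2ULL)) - 1.0;
    double z = 2.0 * u01(splitmix64(h ^ 0x3ULL)) - 1.0;
    double n2 = x * x + y * y + z * z;
    if (n2 <= 1.0 && n2 > 1e-12) {
      double inv = 1.0 / std::sqrt(n2);
      g[0] = x * inv; g[1] = y * inv; g[2] = z * inv;
      return;
    }
  }
}

// quintic smoothstep 6t^5 - 15t^4 + 10t^3 (C2-continuous fade)
static inline double fade(double t) {
  return t * t * t * (t * (t * 6.0 - 15.0) + 10.0);
}

static double noise3(uint64_t seed, double cell, double x, double y, double z) {
  double px = x / cell, py = y / cell, pz = z / cell;
  double fx0 = std::floor(px), fy0 = std::floor(py), fz0 = std::floor(pz);
  int64_t ix = (int64_t)fx0, iy = (int64_t)fy0, iz = (int64_t)fz0;
  double dx = px - fx0, dy = py - fy0, dz = pz - fz0;
  double wx[2] = {1.0 - fade(dx), fade(dx)};
  double wy[2] = {1.0 - fade(dy), fade(dy)};
  double wz[2] = {1.0 - fade(dz), fade(dz)};
  double val = 0.0, g[3];
  for (int cx = 0; cx < 2; ++cx)
    for (int cy = 0; cy < 2; ++cy)
      for (int cz = 0; cz < 2; ++cz) {
        lattice_gradient(seed, ix + cx, iy + cy, iz + cz, g);
        double dot = g[0] * (dx - cx) + g[1] * (dy - cy) + g[2] * (dz - cz);
        val += wx[cx] * wy[cy] * wz[cz] * dot;
      }
  return val;
}

// per-octave seed: decorrelates octaves that share lattice points
static inline uint64_t octave_seed(uint64_t seed, int octave) {
  return splitmix64(seed + 0x517CC1B727220A95ULL * (uint64_t)(octave + 1));
}

static double fractal3(uint64_t seed, double base_cell, int n_oct, double pers,
                       double x, double y, double z) {
  double amp = 1.0, cell = base_cell, total = 0.0, norm = 0.0;
  for (int i = 0; i < n_oct; ++i) {
    total += amp * noise3(octave_seed(seed, i), cell, x, y, z);
    norm += amp;
    amp *= pers;
    cell *= 0.5;
  }
  return total / norm;
}

// [[Rcpp::export]]
NumericMatrix cpp_perlin_gradients(int seed, IntegerMatrix ijk, int octave) {
  int n = ijk.nrow();
  NumericMatrix out(n, 3);
  uint64_t s = octave_seed((uint64_t)seed, octave);
  double g[3];
  for (int r = 0; r < n; ++r) {
    lattice_gradient(s, ijk(r, 0), ijk(r, 1), ijk(r, 2), g);
    out(r, 0) = g[0]; out(r, 1) = g[1]; out(r, 2) = g[2];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_perlin_noise(int seed, double cell, NumericMatrix pts,
                               int octave) {
  int n = pts.nrow();
  NumericVector out(n);
  uint64_t s = octave_seed((uint64_t)seed, octave);
  for (int r = 0; r < n; ++r)
    out[r] = noise3(s, cell, pts(r, 0), pts(r, 1), pts(r, 2));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fractal_noise(int seed, double base_cell, int n_oct,
                                double pers, NumericMatrix pts) {
  int n = pts.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; ++r)
    out[r] = fractal3((uint64_t)seed, base_cell, n_oct, pers,
                      pts(r, 0), pts(r, 1), pts(r, 2));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_field(int seed, double base_cell, int n_oct,
                               double pers, IntegerVector dims, double spacing,
                               NumericVector origin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + (k + 0.5) * spacing;
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + (j + 0.5) * spacing;
      for (int i = 0; i < nx; ++i) {
        double x = origin[0] + (i + 0.5) * spacing;
        out[idx++] = fractal3((uint64_t)seed, base_cell, n_oct, pers, x, y, z);
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
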