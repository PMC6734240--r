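#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Voxel-level primitives for 3-D stacks stored as R arrays dim = c(nx, ny, nz)
// (x fastest). All loops are zero-padded at the borders.

static void conv_axis(const double *in, double *out,
                      int nx, int ny, int nz,
                      const double *k, int klen, int axis) {
  int h = klen / 2;                // kernel is odd-length, centred
  long nxy = (long)nx * ny;
  if (axis == 0) {
    int xa = std::min(nx, h), xb = std::max(xa, nx - h);
    for (long z = 0; z < nz; ++z)
      for (long y = 0; y < ny; ++y) {
        const double *row = in + z * nxy + y * nx;
        double *orow = out + z * nxy + y * nx;
        for (int x = 0; x < xa; ++x) {
          double s = 0.0;
          int t0 = std::max(0, h - x), t1 = std::min(klen, nx - x + h);
          for (int t = t0; t < t1; ++t) s += k[t] * row[x + t - h];
          orow[x] = s;
        }
        for (int x = xa; x < xb; ++x) {      // interior: full kernel
          double s = 0.0;
          const double *p = row + x - h;
          for (int t = 0; t < klen; ++t) s += k[t] * p[t];
          orow[x] = s;
        }
        for (int x = xb; x < nx; ++x) {
          double s = 0.0;
          int t0 = std::max(0, h - x), t1 = std::min(klen, nx - x + h);
          for (int t = t0; t < t1; ++t) s += k[t] * row[x + t - h];
          orow[x] = s;
        }
      }
  } else if (axis == 1) {
    // accumulate whole contiguous rows: out[.,y,.] += k[t] * in[.,y+t-h,.]
    for (long z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        double *orow = out + z * nxy + (long)y * nx;
        std::fill(orow, orow + nx, 0.0);
        int t0 = std::max(0, h - y), t1 = std::min(klen, ny - y + h);
        for (int t = t0; t < t1; ++t) {
          const double kt = k[t];
          const double *row = in + z * nxy + (long)(y + t - h) * nx;
          for (int x = 0; x < nx; ++x) orow[x] += kt * row[x];
        }
      }
  } else {
    for (int z = 0; z < nz; ++z) {
      double *oplane = out + (long)z * nxy;
      std::fill(oplane, oplane + nxy, 0.0);
      int t0 = std::max(0, h - z), t1 = std::min(klen, nz - z + h);
      for (int t = t0; t < t1; ++t) {
        const double kt = k[t];
        const double *plane = in + (long)(z + t - h) * nxy;
        for (long i = 0; i < nxy; ++i) oplane[i] += kt * plane[i];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv_sep3_cpp(NumericVector x, IntegerVector dim,
                            NumericVector kx, NumericVector ky, NumericVector kz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  if ((long)x.size() != n) stop("array length does not match dim");
  NumericVector a(n), b(n);
  conv_axis(REAL(x), REAL(a), nx, ny, nz, REAL(kx), kx.size(), 0);
  conv_axis(REAL(a), REAL(b), nx, ny, nz, REAL(ky), ky.size(), 1);
  conv_axis(REAL(b), REAL(a), nx, ny, nz, REAL(kz), kz.size(), 2);
  a.attr("dim") = dim;
  return a;
}

// Full damped Richardson-Lucy loop for one slab and one separable kernel.
// Model: y ~ Pois(Hx + b); update x *= (H^T(y/(Hx+b)) / H^T 1)^gam.
// Stops when the relative L2 change between iterates drops below qct.
// [[Rcpp::export]]
List rl_loop_cpp(NumericVector y, IntegerVector dim,
                 NumericVector kx, NumericVector ky, NumericVector kz,
                 double b, double gam, double qct, int max_iter,
                 bool trace) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  const double eps = 2.220446e-16;
  NumericVector x(n), w(n), t1(n), t2(n);
  double *X = REAL(x), *W = REAL(w), *A = REAL(t1), *B = REAL(t2);
  const double *Y = REAL(y);
  double s0 = 0.0;
  for (long i = 0; i < n; ++i) { X[i] = std::max(Y[i] - b, 0.0); s0 += X[i]; }
  std::vector<double> ll;
  int it = 0; double rel = 0.0;
  if (s0 > 0.0) {
    std::fill(W, W + n, 1.0);
    conv_axis(W, A, nx, ny, nz, REAL(kx), kx.size(), 0);
    conv_axis(A, B, nx, ny, nz, REAL(ky), ky.size(), 1);
    conv_axis(B, W, nx, ny, nz, REAL(kz), kz.size(), 2);
    rel = 1.0;
    while (it < max_iter) {
      ++it;
      conv_axis(X, A, nx, ny, nz, REAL(kx), kx.size(), 0);
      conv_axis(A, B, nx, ny, nz, REAL(ky), ky.size(), 1);
      conv_axis(B, A, nx, ny, nz, REAL(kz), kz.size(), 2);   // A = Hx
      double l = 0.0;
      if (trace) {
        for (long i = 0; i < n; ++i) {
          double hb = A[i] + b;
          l += Y[i] * std::log(std::max(hb, eps)) - hb;
        }
        ll.push_back(l);
      }
      for (long i = 0; i < n; ++i)
        A[i] = Y[i] / std::max(A[i] + b, eps);
      conv_axis(A, B, nx, ny, nz, REAL(kx), kx.size(), 0);
      conv_axis(B, A, nx, ny, nz, REAL(ky), ky.size(), 1);
      conv_axis(A, B, nx, ny, nz, REAL(kz), kz.size(), 2);   // B = H^T ratio
      double num = 0.0, den = 0.0;
      for (long i = 0; i < n; ++i) {
        double u = B[i] / std::max(W[i], eps);
        double xn = X[i] * (gam == 1.0 ? u : std::pow(u, gam));
        double d = xn - X[i];
        num += d * d; den += X[i] * X[i];
        X[i] = xn;
      }
      rel = std::sqrt(num) / std::max(std::sqrt(den), eps);
      if (rel < qct) break;
    }
  }
  x.attr("dim") = dim;
  return List::create(_["x"] = x, _["iterations"] = it,
                      _["final_change"] = rel,
                      _["converged"] = rel < qct,
                      _["loglik"] = wrap(ll));
}

// 3-D connected-component labelling (26- or 6-connectivity), BFS.
// [[Rcpp::export]]
IntegerVector label3d_cpp(IntegerVector mask, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz, nxy = (long)nx * ny;
  if ((long)mask.size() != n) stop("array length does not match dim");
  IntegerVector lab(n, 0);
  std::vector<long> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        if (connectivity == 6 && (std::abs(dx) + std::abs(dy) + std::abs(dz) != 1))
          continue;
        offs.push_back(dx + (long)dy * nx + (long)dz * nxy);
      }
  const int *m = INTEGER(mask);
  int *L = INTEGER(lab);
  int cur = 0;
  std::vector<long> stack;
  for (long i = 0; i < n; ++i) {
    if (!m[i] || L[i]) continue;
    ++cur;
    stack.clear();
    stack.push_back(i);
    L[i] = cur;
    while (!stack.empty()) {
      long v = stack.back(); stack.pop_back();
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / nxy);
      for (size_t s = 0; s < offs.size(); ++s) {
        long dv = offs[s];
        // decode neighbour coordinates to reject wrap-around
        long dz0 = dv >= 0 ? (dv + nxy / 2) / nxy : -((-dv + nxy / 2) / nxy);
        long rem = dv - dz0 * nxy;
        long dy0 = rem >= 0 ? (rem + nx / 2) / nx : -((-rem + nx / 2) / nx);
        long dx0 = rem - dy0 * nx;
        int xn = x + (int)dx0, yn = y + (int)dy0, zn = z + (int)dz0;
        if (xn < 0 || xn >= nx || yn < 0 || yn >= ny || zn < 0 || zn >= nz) continue;
        long w = v + dv;
        if (m[w] && !L[w]) { L[w] = cur; stack.push_back(w); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Fill internal holes slice by slice: 4-connected background flood fill from
// the slice border; unreached background pixels are holes.
// [[Rcpp::export]]
IntegerVector fill_holes_slices_cpp(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nxy = (long)nx * ny;
  IntegerVector out = clone(mask);
  int *M = INTEGER(out);
  std::vector<unsigned char> vis(nxy);
  std::vector<long> stack;
  for (int z = 0; z < nz; ++z) {
    int *sl = M + (long)z * nxy;
    std::fill(vis.begin(), vis.end(), 0);
    stack.clear();
    for (int x = 0; x < nx; ++x) {
      if (!sl[x]) { vis[x] = 1; stack.push_back(x); }
      long b = (long)(ny - 1) * nx + x;
      if (!sl[b] && !vis[b]) { vis[b] = 1; stack.push_back(b); }
    }
    for (int y = 0; y < ny; ++y) {
      long l = (long)y * nx, r = l + nx - 1;
      if (!sl[l] && !vis[l]) { vis[l] = 1; stack.push_back(l); }
      if (!sl[r] && !vis[r]) { vis[r] = 1; stack.push_back(r); }
    }
    while (!stack.empty()) {
      long v = stack.back(); stack.pop_back();
      int x = (int)(v % nx), y = (int)(v / nx);
      const int dx[4] = {1, -1, 0, 0}, dy[4] = {0, 0, 1, -1};
      for (int s = 0; s < 4; ++s) {
        int xn = x + dx[s], yn = y + dy[s];
        if (xn < 0 || xn >= nx || yn < 0 || yn >= ny) continue;
        long w = (long)yn * nx + xn;
        if (!sl[w] && !vis[w]) { vis[w] = 1; stack.push_back(w); }
      }
    }
    for (long i = 0; i < nxy; ++i)
      if (!sl[i] && !vis[i]) sl[i] = 1;
  }
  out.attr("dim") = dim;
  return out;
}
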