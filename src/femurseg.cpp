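#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// BFS labelling of foreground components; returns a logical array keeping
// only the largest component (ties: first component in scan order,
// axis 1 fastest).
// [[Rcpp::export]]
LogicalVector cc_largest(IntegerVector mask, int connectivity) {
  IntegerVector dims = mask.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;

  std::vector<int> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        off.push_back(dx); off.push_back(dy); off.push_back(dz);
      }

  std::vector<int> label(n, 0);
  std::vector<R_xlen_t> sizes(1, 0);
  int nlab = 0;
  std::queue<R_xlen_t> q;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || label[i] != 0) continue;
    ++nlab;
    sizes.push_back(0);
    label[i] = nlab;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      ++sizes[nlab];
      int cz = (int)(cur / ((R_xlen_t)nx * ny));
      int rem = (int)(cur % ((R_xlen_t)nx * ny));
      int cy = rem / nx, cx = rem % nx;
      for (size_t t = 0; t < off.size(); t += 3) {
        int xx = cx + off[t], yy = cy + off[t + 1], zz = cz + off[t + 2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t j = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[j] != 0 && label[j] == 0) {
          label[j] = nlab;
          q.push(j);
        }
      }
    }
  }

  int best = 1;
  for (int l = 2; l <= nlab; ++l)
    if (sizes[l] > sizes[best]) best = l;   // strict: ties keep first label

  LogicalVector keep(n);
  for (R_xlen_t i = 0; i < n; ++i) keep[i] = (label[i] == best);
  keep.attr("dim") = dims;
  return keep;
}

// exact nearest-neighbour Euclidean distance from every row of `from` to
// the point set `to` (columns = physical x, y, z in mm)
// [[Rcpp::export]]
NumericVector directed_surface_dists(NumericMatrix from, NumericMatrix to) {
  const int n = from.nrow(), m = to.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double fx = from(i, 0), fy = from(i, 1), fz = from(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double dx = fx - to(j, 0), dy = fy - to(j, 1), dz = fz - to(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

#define USE_FC_LEN_T
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif

// gather one kernel tap of the input into a contiguous n x cin buffer,
// reading the input through an implicit zero border of width `pad`
// (off = tap offset * dilation - pad is the source shift per axis)
static void gather_tap(const double *px, double *buf, int cin,
                       int n1, int n2, int n3, int o1, int o2, int o3,
                       int f1, int f2, int f3) {
  const R_xlen_t n = (R_xlen_t)o1 * o2 * o3;
  const int i0 = std::max(0, -f1), i1 = std::min(o1, n1 - f1);
  for (int c = 0; c < cin; ++c) {
    double *dst = buf + (R_xlen_t)c * n;
    const double *src = px + (R_xlen_t)c * n1 * n2 * n3;
    for (int k = 0; k < o3; ++k) {
      const int sk = k + f3;
      if (sk < 0 || sk >= n3) {
        std::fill(dst, dst + (R_xlen_t)o1 * o2, 0.0);
        dst += (R_xlen_t)o1 * o2;
        continue;
      }
      const double *srck = src + (R_xlen_t)sk * n1 * n2;
      for (int j = 0; j < o2; ++j) {
        const int sj = j + f2;
        if (sj < 0 || sj >= n2) {
          std::fill(dst, dst + o1, 0.0);
          dst += o1;
          continue;
        }
        const double *row = srck + (R_xlen_t)sj * n1;
        if (i0 > 0) std::fill(dst, dst + i0, 0.0);
        if (i1 > i0) std::copy(row + i0 + f1, row + i1 + f1, dst + i0);
        if (i1 < o1) std::fill(dst + std::max(i1, i0), dst + o1, 0.0);
        dst += o1;
      }
    }
  }
}

static void scatter_tap_add(double *px, const double *buf, int cin,
                            int n1, int n2, int n3, int o1, int o2, int o3,
                            int f1, int f2, int f3) {
  const R_xlen_t n = (R_xlen_t)o1 * o2 * o3;
  const int i0 = std::max(0, -f1), i1 = std::min(o1, n1 - f1);
  for (int c = 0; c < cin; ++c) {
    const double *src0 = buf + (R_xlen_t)c * n;
    double *dst0 = px + (R_xlen_t)c * n1 * n2 * n3;
    for (int k = 0; k < o3; ++k) {
      const int sk = k + f3;
      if (sk < 0 || sk >= n3) continue;
      for (int j = 0; j < o2; ++j) {
        const int sj = j + f2;
        if (sj < 0 || sj >= n2) continue;
        const double *src = src0 + ((R_xlen_t)k * o2 + j) * o1;
        double *row = dst0 + (R_xlen_t)sk * n1 * n2 + (R_xlen_t)sj * n1 + f1;
        for (int i = i0; i < i1; ++i) row[i] += src[i];
      }
    }
  }
}

// 3^d convolution with dilation `dil` and zero padding of width `pad`
// (0 = valid, dil = same size); tap-by-tap BLAS accumulation.
// Weights: (3^d * cin) x cout, tap-major, axis-1 offsets fastest.
// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector x, NumericMatrix w,
                           NumericVector bias, int dil, int pad) {
  IntegerVector xd = x.attr("dim");
  const int d = xd.size() - 1;
  const int cin = xd[d];
  const int cout = w.ncol();
  const int krows = w.nrow();
  const int n1 = xd[0], n2 = xd[1], n3 = (d == 3) ? xd[2] : 1;
  const int o1 = n1 + 2 * pad - 2 * dil, o2 = n2 + 2 * pad - 2 * dil;
  const int o3 = (d == 3) ? n3 + 2 * pad - 2 * dil : 1;
  const int intn = o1 * o2 * o3;
  const R_xlen_t n = (R_xlen_t)intn;
  NumericVector y(n * cout);
  double *py = y.begin();
  for (int c = 0; c < cout; ++c)
    std::fill(py + c * n, py + (c + 1) * n, bias[c]);
  std::vector<double> buf(n * cin);
  const double one = 1.0;
  int tap = 0;
  const int nd3 = (d == 3) ? 3 : 1;
  for (int a3 = 0; a3 < nd3; ++a3)
    for (int a2 = 0; a2 < 3; ++a2)
      for (int a1 = 0; a1 < 3; ++a1, ++tap) {
        gather_tap(x.begin(), buf.data(), cin, n1, n2, n3, o1, o2, o3,
                   a1 * dil - pad, a2 * dil - pad,
                   (d == 3) ? a3 * dil - pad : 0);
        F77_CALL(dgemm)("N", "N", &intn, &cout, &cin, &one, buf.data(),
                        &intn, &w(tap * cin, 0), &krows, &one, py, &intn
                        FCONE FCONE);
      }
  if (d == 2) y.attr("dim") = IntegerVector::create(o1, o2, cout);
  else y.attr("dim") = IntegerVector::create(o1, o2, o3, cout);
  return y;
}

// gradients of conv_fwd_cpp: list(dx, dW, db)
// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector x, NumericMatrix w, NumericVector dy,
                  int dil, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector yd = dy.attr("dim");
  const int d = xd.size() - 1;
  const int cin = xd[d];
  const int cout = w.ncol();
  const int krows = w.nrow();
  const int n1 = xd[0], n2 = xd[1], n3 = (d == 3) ? xd[2] : 1;
  const int o1 = yd[0], o2 = yd[1], o3 = (d == 3) ? yd[2] : 1;
  const int intn = o1 * o2 * o3;
  const R_xlen_t n = (R_xlen_t)intn;
  NumericMatrix dW(krows, cout);
  NumericVector db(cout);
  NumericVector dx((R_xlen_t)n1 * n2 * n3 * cin);
  dx.attr("dim") = xd;
  const double *pdy = dy.begin();
  for (int c = 0; c < cout; ++c) {
    double acc = 0.0;
    const double *col = pdy + c * n;
    for (R_xlen_t i = 0; i < n; ++i) acc += col[i];
    db[c] = acc;
  }
  std::vector<double> buf(n * cin);
  const double one = 1.0, zero = 0.0;
  int tap = 0;
  const int nd3 = (d == 3) ? 3 : 1;
  for (int a3 = 0; a3 < nd3; ++a3)
    for (int a2 = 0; a2 < 3; ++a2)
      for (int a1 = 0; a1 < 3; ++a1, ++tap) {
        const int f1 = a1 * dil - pad, f2 = a2 * dil - pad;
        const int f3 = (d == 3) ? a3 * dil - pad : 0;
        gather_tap(x.begin(), buf.data(), cin, n1, n2, n3, o1, o2, o3,
                   f1, f2, f3);
        F77_CALL(dgemm)("T", "N", &cin, &cout, &intn, &one, buf.data(),
                        &intn, pdy, &intn, &zero, &dW(tap * cin, 0), &krows
                        FCONE FCONE);
        F77_CALL(dgemm)("N", "T", &intn, &cin, &cout, &one, pdy, &intn,
                        &w(tap * cin, 0), &krows, &zero, buf.data(), &intn
                        FCONE FCONE);
        scatter_tap_add(dx.begin(), buf.data(), cin, n1, n2, n3,
                        o1, o2, o3, f1, f2, f3);
      }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// transposed convolution, kernel 2^d, stride 2; weights are a
// (2^d * cin) x cout matrix, tap-major with axis-1 offsets fastest
// [[Rcpp::export]]
NumericVector upconv_fwd_cpp(NumericVector x, NumericMatrix w,
                             NumericVector bias) {
  IntegerVector xd = x.attr("dim");
  const int d = xd.size() - 1;
  const int cin = xd[d];
  const int cout = w.ncol();
  const int krows = w.nrow();
  const int n1 = xd[0], n2 = xd[1], n3 = (d == 3) ? xd[2] : 1;
  const int intn = n1 * n2 * n3;
  const R_xlen_t n = (R_xlen_t)intn;
  const int y1 = 2 * n1, y2 = 2 * n2, y3 = (d == 3) ? 2 * n3 : 1;
  NumericVector y((R_xlen_t)y1 * y2 * y3 * cout);
  double *py = y.begin();
  std::fill(py, py + y.size(), 0.0);
  std::vector<double> buf(n * cout);
  const double one = 1.0, zero = 0.0;
  int tap = 0;
  const int nd3 = (d == 3) ? 2 : 1;
  for (int a3 = 0; a3 < nd3; ++a3)
    for (int a2 = 0; a2 < 2; ++a2)
      for (int a1 = 0; a1 < 2; ++a1, ++tap) {
        F77_CALL(dgemm)("N", "N", &intn, &cout, &cin, &one, x.begin(), &intn,
                        &w(tap * cin, 0), &krows, &zero, buf.data(), &intn
                        FCONE FCONE);
        for (int c = 0; c < cout; ++c) {
          const double *src = buf.data() + (R_xlen_t)c * n;
          double *dst = py + (R_xlen_t)c * y1 * y2 * y3;
          for (int k = 0; k < n3; ++k)
            for (int j = 0; j < n2; ++j) {
              double *row = dst + (R_xlen_t)(2 * k + a3) * y1 * y2 +
                (R_xlen_t)(2 * j + a2) * y1 + a1;
              const double *s = src + ((R_xlen_t)k * n2 + j) * n1;
              for (int i = 0; i < n1; ++i) row[2 * i] = s[i];
            }
        }
      }
  for (int c = 0; c < cout; ++c) {
    double *dst = py + (R_xlen_t)c * y1 * y2 * y3;
    const double b = bias[c];
    for (R_xlen_t i = 0; i < (R_xlen_t)y1 * y2 * y3; ++i) dst[i] += b;
  }
  if (d == 2) y.attr("dim") = IntegerVector::create(y1, y2, cout);
  else y.attr("dim") = IntegerVector::create(y1, y2, y3, cout);
  return y;
}

// [[Rcpp::export]]
List upconv_bwd_cpp(NumericVector x, NumericMatrix w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  const int d = xd.size() - 1;
  const int cin = xd[d];
  const int cout = w.ncol();
  const int krows = w.nrow();
  const int n1 = xd[0], n2 = xd[1], n3 = (d == 3) ? xd[2] : 1;
  const int intn = n1 * n2 * n3;
  const R_xlen_t n = (R_xlen_t)intn;
  const int y1 = 2 * n1, y2 = 2 * n2, y3 = (d == 3) ? 2 * n3 : 1;
  NumericMatrix dW(krows, cout);
  NumericVector db(cout);
  NumericVector dx((R_xlen_t)intn * cin);
  dx.attr("dim") = xd;
  std::fill(dx.begin(), dx.end(), 0.0);
  const double *pdy = dy.begin();
  for (int c = 0; c < cout; ++c) {
    double acc = 0.0;
    const double *col = pdy + (R_xlen_t)c * y1 * y2 * y3;
    for (R_xlen_t i = 0; i < (R_xlen_t)y1 * y2 * y3; ++i) acc += col[i];
    db[c] = acc;
  }
  std::vector<double> buf(n * cout);
  const double one = 1.0, zero = 0.0;
  int tap = 0;
  const int nd3 = (d == 3) ? 2 : 1;
  for (int a3 = 0; a3 < nd3; ++a3)
    for (int a2 = 0; a2 < 2; ++a2)
      for (int a1 = 0; a1 < 2; ++a1, ++tap) {
        for (int c = 0; c < cout; ++c) {
          double *dst = buf.data() + (R_xlen_t)c * n;
          const double *src = pdy + (R_xlen_t)c * y1 * y2 * y3;
          for (int k = 0; k < n3; ++k)
            for (int j = 0; j < n2; ++j) {
              const double *row = src + (R_xlen_t)(2 * k + a3) * y1 * y2 +
                (R_xlen_t)(2 * j + a2) * y1 + a1;
              double *t = dst + ((R_xlen_t)k * n2 + j) * n1;
              for (int i = 0; i < n1; ++i) t[i] = row[2 * i];
            }
        }
        F77_CALL(dgemm)("T", "N", &cin, &cout, &intn, &one, x.begin(), &intn,
                        buf.data(), &intn, &zero, &dW(tap * cin, 0), &krows
                        FCONE FCONE);
        F77_CALL(dgemm)("N", "T", &intn, &cin, &cout, &one, buf.data(),
                        &intn, &w(tap * cin, 0), &krows, &one, dx.begin(),
                        &intn FCONE FCONE);
      }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double *px = x.begin();
  double *py = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) py[i] = px[i] > 0 ? px[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector y, NumericVector dy) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double *py = y.begin(), *pdy = dy.begin();
  double *pdx = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) pdx[i] = py[i] > 0 ? pdy[i] : 0;
  return dx;
}

// 2^d max-pooling, stride 2; returns pooled tensor and 1-based linear
// argmax indices (ties to the first tap in scan order)
// [[Rcpp::export]]
List pool_fwd_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int d = xd.size() - 1;
  const int cin = xd[d];
  const int n1 = xd[0], n2 = xd[1], n3 = (d == 3) ? xd[2] : 1;
  const int o1 = n1 / 2, o2 = n2 / 2, o3 = (d == 3) ? n3 / 2 : 1;
  const R_xlen_t n = (R_xlen_t)o1 * o2 * o3;
  NumericVector y(n * cin);
  NumericVector arg(n * cin);
  const double *px = x.begin();
  double *py = y.begin();
  double *pa = arg.begin();
  const int k3 = (d == 3) ? 2 : 1;
  R_xlen_t pos = 0;
  for (int c = 0; c < cin; ++c) {
    const double *src = px + (R_xlen_t)c * n1 * n2 * n3;
    for (int k = 0; k < o3; ++k)
      for (int j = 0; j < o2; ++j)
        for (int i = 0; i < o1; ++i) {
          double best = R_NegInf;
          R_xlen_t bidx = 0;
          for (int dz = 0; dz < k3; ++dz)
            for (int dyy = 0; dyy < 2; ++dyy)
              for (int dxx = 0; dxx < 2; ++dxx) {
                R_xlen_t idx = (R_xlen_t)(2 * k + dz) * n1 * n2 +
                  (R_xlen_t)(2 * j + dyy) * n1 + (2 * i + dxx);
                if (src[idx] > best) { best = src[idx]; bidx = idx; }
              }
          py[pos] = best;
          pa[pos] = (double)((R_xlen_t)c * n1 * n2 * n3 + bidx + 1);
          ++pos;
        }
  }
  if (d == 2) y.attr("dim") = IntegerVector::create(o1, o2, cin);
  else y.attr("dim") = IntegerVector::create(o1, o2, o3, cin);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector pool_bwd_cpp(NumericVector dy, NumericVector argmax,
                           IntegerVector x_dim) {
  R_xlen_t total = 1;
  for (int i = 0; i < x_dim.size(); ++i) total *= x_dim[i];
  NumericVector dx(total);
  dx.attr("dim") = x_dim;
  const double *pdy = dy.begin();
  const double *pa = argmax.begin();
  double *pdx = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    pdx[(R_xlen_t)pa[i] - 1] += pdy[i];
  return dx;
}
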