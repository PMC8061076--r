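#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Coverage-weighted local-polynomial smoother for one chromosome.
//
// For each locus i the window is the smallest symmetric half-width h with
// h >= min_width/2 and >= min_loci loci inside [pos_i - h, pos_i + h]
// (one-sided truncation at chromosome ends falls out of the locus-count
// rule). Weights are tricube in scaled distance times read coverage; the
// fitted value at the locus is clamped to [0,1]. Loci whose window holds no
// covered locus for a sample get NA there.
//
// The accumulation loop runs over samples innermost on transposed copies of
// the count matrices so the weighted-moment updates vectorize across
// samples.

static bool solve_sym(double A[3][3], double b[3], int dim, double out[3]) {
  // Gaussian elimination with partial pivoting on a dim x dim system
  double m[3][4];
  for (int r = 0; r < dim; ++r) {
    for (int c = 0; c < dim; ++c) m[r][c] = A[r][c];
    m[r][dim] = b[r];
  }
  for (int col = 0; col < dim; ++col) {
    int piv = col;
    for (int r = col + 1; r < dim; ++r)
      if (std::fabs(m[r][col]) > std::fabs(m[piv][col])) piv = r;
    if (std::fabs(m[piv][col]) < 1e-12) return false;
    if (piv != col)
      for (int c = 0; c <= dim; ++c) std::swap(m[piv][c], m[col][c]);
    for (int r = col + 1; r < dim; ++r) {
      double f = m[r][col] / m[col][col];
      for (int c = col; c <= dim; ++c) m[r][c] -= f * m[col][c];
    }
  }
  for (int r = dim - 1; r >= 0; --r) {
    double s = m[r][dim];
    for (int c = r + 1; c < dim; ++c) s -= m[r][c] * out[c];
    out[r] = s / m[r][r];
  }
  return true;
}

// [[Rcpp::export]]
NumericMatrix smooth_chr_cpp(NumericVector pos, IntegerMatrix M,
                             IntegerMatrix Cov, double min_width,
                             int min_loci, int degree) {
  const int n = pos.size();
  const int ns = M.ncol();
  NumericMatrix out(n, ns);
  if (n == 0) return out;
  if (min_loci > n) min_loci = n;  // whole-chromosome window

  // sample-major transposed coverage and methylation fraction
  std::vector<double> covT((size_t)n * ns), ratioT((size_t)n * ns);
  for (int j = 0; j < n; ++j) {
    for (int s = 0; s < ns; ++s) {
      double c = Cov(j, s);
      covT[(size_t)j * ns + s] = c;
      ratioT[(size_t)j * ns + s] = c > 0 ? M(j, s) / c : 0.0;
    }
  }

  std::vector<double> sw(ns), sx(ns), sx2(ns), sx3(ns), sx4(ns),
      sy(ns), sxy(ns), sx2y(ns);
  std::vector<int> npos(ns);

  for (int i = 0; i < n; ++i) {
    // half-width from the min_loci-th nearest locus (two-pointer expansion)
    int lo = i, hi = i;
    double h_cnt = 0.0;
    int cnt = 1;
    while (cnt < min_loci) {
      double dl = (lo > 0) ? pos[i] - pos[lo - 1] : R_PosInf;
      double dr = (hi < n - 1) ? pos[hi + 1] - pos[i] : R_PosInf;
      if (dl <= dr) { --lo; h_cnt = dl; } else { ++hi; h_cnt = dr; }
      ++cnt;
    }
    double h = std::max(h_cnt, min_width / 2.0);
    while (lo > 0 && pos[i] - pos[lo - 1] <= h) --lo;
    while (hi < n - 1 && pos[hi + 1] - pos[i] <= h) ++hi;
    const double hh = h * (1.0 + 1e-9) + 1e-12;  // boundary loci keep weight > 0

    std::fill(sw.begin(), sw.end(), 0.0);
    std::fill(sx.begin(), sx.end(), 0.0);
    std::fill(sx2.begin(), sx2.end(), 0.0);
    std::fill(sx3.begin(), sx3.end(), 0.0);
    std::fill(sx4.begin(), sx4.end(), 0.0);
    std::fill(sy.begin(), sy.end(), 0.0);
    std::fill(sxy.begin(), sxy.end(), 0.0);
    std::fill(sx2y.begin(), sx2y.end(), 0.0);
    std::fill(npos.begin(), npos.end(), 0);

    for (int j = lo; j <= hi; ++j) {
      const double x = (pos[j] - pos[i]) / hh;
      const double u = std::fabs(x);
      const double t = 1.0 - u * u * u;
      const double k = t * t * t;
      const double x2 = x * x;
      const double *cv = &covT[(size_t)j * ns];
      const double *ry = &ratioT[(size_t)j * ns];
      for (int s = 0; s < ns; ++s) {
        const double w = k * cv[s];
        const double wx = w * x;
        const double wx2 = w * x2;
        const double y = ry[s];
        sw[s] += w; sx[s] += wx; sx2[s] += wx2;
        sx3[s] += wx2 * x; sx4[s] += wx2 * x2;
        sy[s] += w * y; sxy[s] += wx * y; sx2y[s] += wx2 * y;
        npos[s] += cv[s] > 0 ? 1 : 0;
      }
    }

    for (int s = 0; s < ns; ++s) {
      if (npos[s] == 0) { out(i, s) = NA_REAL; continue; }
      int deg = degree;
      if (deg > npos[s] - 1) deg = npos[s] - 1;
      if (deg < 0) deg = 0;
      double fit = NA_REAL;
      while (deg >= 0) {
        if (deg == 0) { fit = sy[s] / sw[s]; break; }
        double A[3][3], b[3], coef[3];
        if (deg == 1) {
          A[0][0] = sw[s];  A[0][1] = sx[s];
          A[1][0] = sx[s];  A[1][1] = sx2[s];
          b[0] = sy[s]; b[1] = sxy[s];
          if (solve_sym(A, b, 2, coef)) { fit = coef[0]; break; }
        } else {
          A[0][0] = sw[s];  A[0][1] = sx[s];  A[0][2] = sx2[s];
          A[1][0] = sx[s];  A[1][1] = sx2[s]; A[1][2] = sx3[s];
          A[2][0] = sx2[s]; A[2][1] = sx3[s]; A[2][2] = sx4[s];
          b[0] = sy[s]; b[1] = sxy[s]; b[2] = sx2y[s];
          if (solve_sym(A, b, 3, coef)) { fit = coef[0]; break; }
        }
        --deg;  // singular system: fall back to a lower degree
      }
      if (fit < 0.0) fit = 0.0;
      if (fit > 1.0) fit = 1.0;
      out(i, s) = fit;
    }
  }
  return out;
}
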